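#' Construct a multi-channel EEG recording
#'
#' A recording bundles a samples-by-channels matrix of voltages (microvolts)
#' with its sampling rate, stimulus onset indices and channel names. Event
#' onsets are 0-based sample indices, so an event at onset 0 starts at the
#' first sample.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param events Integer vector of 0-based onset sample indices.
#' @param channel_names Character vector, one name per column of `data`.
#' @return An object of class `erp_recording`.
#' @export
recording <- function(data, fs, events = integer(), channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  if (any(!is.finite(data)))
    stop("recording data contains non-finite values")
  events <- as.integer(events)
  if (length(events) && (any(events < 0L) || any(events >= nrow(data))))
    stop("event onsets must lie within [0, n_samples)")
  if (is.null(channel_names)) {
    channel_names <- colnames(data)
    if (is.null(channel_names))
      channel_names <- paste0("ch", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data))
    stop("`channel_names` length must equal the number of channels")
  colnames(data) <- channel_names
  structure(
    list(data = data, fs = fs, events = events, channel_names = channel_names),
    class = "erp_recording"
  )
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf(
    "<erp_recording> %d samples x %d channels @ %g Hz, %d events\n",
    nrow(x$data), ncol(x$data), x$fs, length(x$events)
  ))
  invisible(x)
}

#' Read a recording from a CSV matrix
#'
#' The file must hold a samples-by-channels numeric matrix, one row per
#' sample, with an optional single header row of channel names. Decimal
#' separator is ".".
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz to attach to the recording.
#' @param has_header Logical; `TRUE` if the first row holds channel names.
#' @param events Optional 0-based event onsets to attach.
#' @return An `erp_recording`.
#' @export
load_csv <- function(path, fs, has_header = FALSE, events = integer()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty CSV file: ", path)
  header <- NULL
  if (isTRUE(has_header)) {
    header <- trimws(strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]])
    lines <- lines[-1L]
    if (!length(lines)) stop("CSV has a header but no data rows: ", path)
  }
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol_expect <- length(cells[[1L]])
  n_cells <- lengths(cells)
  if (any(n_cells != ncol_expect)) {
    bad <- which(n_cells != ncol_expect)[1L]
    stop(sprintf("ragged CSV: row %d has %d columns, expected %d",
                 bad, n_cells[bad], ncol_expect))
  }
  vals <- suppressWarnings(lapply(cells, function(r) as.numeric(trimws(r))))
  bad_rows <- which(vapply(vals, function(v) any(is.na(v)), logical(1L)))
  if (length(bad_rows))
    stop(sprintf("non-numeric cell in CSV row %d", bad_rows[1L]))
  data <- do.call(rbind, vals)
  recording(data, fs = fs, events = events, channel_names = header)
}

#' Write a recording or numeric matrix to CSV
#'
#' Inverse of [load_csv()]: numbers are written with full double precision
#' (17 significant digits) so a save/load round trip is bit-exact.
#'
#' @param x An `erp_recording` or a numeric matrix.
#' @param path Output file path.
#' @param header Logical; write channel names as a first row.
#' @export
save_csv <- function(x, path, header = FALSE) {
  m <- if (inherits(x, "erp_recording")) x$data else as.matrix(x)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (isTRUE(header) && !is.null(colnames(m)))
    writeLines(paste(colnames(m), collapse = ","), con)
  body <- apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Applies a Butterworth band-pass forward and backward (via
#' [signal::filtfilt()]), giving zero phase distortion so component
#' latencies are preserved. The default 4th-order design matches common
#' ERP practice.
#'
#' @param x Numeric vector (a single-channel signal).
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order (of the underlying low/high-pass design).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 2, high = 30, order = 4L) {
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band edges: need 0 < low < high < fs/2")
  if (length(x) <= 3L * 2L * order)
    stop("signal too short for the requested filter order")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filtfilt_padded(function(z) as.numeric(signal::filtfilt(bf, z)),
                  as.numeric(x), pad = min(length(x) - 1L,
                                           as.integer(round(6 * fs / low))))
}

# odd-reflection padding around a zero-phase filter call, suppressing the
# start-up transients the raw forward-backward pass leaves at the edges
filtfilt_padded <- function(filter_fun, x, pad) {
  n <- length(x)
  if (pad < 1L) return(filter_fun(x))
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- filter_fun(c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

#' Anti-aliased integer-ratio downsampling
#'
#' Low-pass filters with a zero-phase FIR (cutoff at 90% of the target
#' Nyquist) and then keeps every `fs_in/fs_out`-th sample. Only integer
#' decimation ratios are supported.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @return Decimated signal of length `floor(length(x) * fs_out / fs_in)`.
#' @export
downsample <- function(x, fs_in, fs_out) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  q <- fs_in / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop(sprintf("non-integer decimation ratio %g/%g", fs_in, fs_out))
  q <- as.integer(round(q))
  if (q == 1L) return(as.numeric(x))
  b <- signal::fir1(30L, 0.9 / q)
  y <- filtfilt_padded(function(z) as.numeric(signal::filtfilt(b, z)),
                       as.numeric(x), pad = min(length(x) - 1L, 93L))
  n_out <- floor(length(x) / q)
  y[seq.int(1L, by = q, length.out = n_out)]
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across channels from each channel.
#' After re-referencing the per-sample channel mean is exactly zero.
#'
#' @param rec An `erp_recording` with at least two channels.
#' @return A re-referenced `erp_recording`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "erp_recording"))
  if (ncol(rec$data) < 2L)
    stop("common average reference is undefined for a single channel")
  out <- rec$data - rowMeans(rec$data)
  recording(out, fs = rec$fs, events = rec$events,
            channel_names = rec$channel_names)
}

#' Cut fixed-length single-channel epochs after each event
#'
#' For each event onset `o` (0-based) the half-open window
#' `[o, o + round(fs * duration_s))` of the chosen channel is extracted.
#'
#' @param rec An `erp_recording` with events.
#' @param channel Channel name or 1-based column index.
#' @param duration_s Epoch length in seconds.
#' @return An `erp_epochs` object: list with `trials` (n_trials x n_samples
#'   matrix), `fs`, `channel`, `duration_s`.
#' @export
extract_epochs <- function(rec, channel = 1L, duration_s = 1.0) {
  stopifnot(inherits(rec, "erp_recording"))
  if (!length(rec$events)) stop("recording has no events")
  if (is.character(channel)) {
    idx <- match(channel, rec$channel_names)
    if (is.na(idx)) stop("unknown channel: ", channel)
  } else idx <- as.integer(channel)
  n_win <- as.integer(round(rec$fs * duration_s))
  if (n_win < 1L) stop("`duration_s` too short for the sampling rate")
  ends <- rec$events + n_win          # exclusive, 0-based
  bad <- which(ends > nrow(rec$data))
  if (length(bad))
    stop("event window(s) exceed recording length for event index(es): ",
         paste(bad, collapse = ", "))
  trials <- t(vapply(rec$events, function(o)
    rec$data[(o + 1L):(o + n_win), idx], numeric(n_win)))
  structure(
    list(trials = trials, fs = rec$fs,
         channel = rec$channel_names[idx], duration_s = duration_s),
    class = "erp_epochs"
  )
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("<erp_epochs> %d trials x %d samples @ %g Hz (channel %s)\n",
              nrow(x$trials), ncol(x$trials), x$fs, x$channel))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Convenience wrapper running, in order: downsample, band-pass, common
#' average reference, epoch extraction — the usual ERP preparation for
#' trials recorded at a higher rate.
#'
#' @param rec An `erp_recording`.
#' @param fs_out Target sampling rate (Hz).
#' @param low,high Band-pass edges (Hz).
#' @param channel Channel to epoch.
#' @param duration_s Epoch length (s).
#' @return An `erp_epochs` object.
#' @export
preprocess_recording <- function(rec, fs_out = 250, low = 2, high = 30,
                                 channel = 1L, duration_s = 1.0) {
  q <- rec$fs / fs_out
  if (abs(q - round(q)) > 1e-9) stop("non-integer decimation ratio")
  ds <- apply(rec$data, 2L, downsample, fs_in = rec$fs, fs_out = fs_out)
  ev <- as.integer(floor(rec$events / round(q)))
  rec2 <- recording(ds, fs = fs_out, events = ev,
                    channel_names = rec$channel_names)
  filt <- apply(rec2$data, 2L, bandpass, fs = fs_out, low = low, high = high)
  rec3 <- recording(filt, fs = fs_out, events = ev,
                    channel_names = rec$channel_names)
  if (ncol(rec3$data) >= 2L) rec3 <- common_average_reference(rec3)
  extract_epochs(rec3, channel = channel, duration_s = duration_s)
}
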