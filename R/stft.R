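#' Short-time Fourier transform configuration
#'
#' Validates a window/hop/FFT combination and pre-checks invertibility.
#' Inversion uses weighted overlap-add with the analysis window as the
#' synthesis window, normalised by the summed squared window; this is exact
#' whenever the sliding sum of squared windows is bounded away from zero
#' (the constant/nonzero overlap-add condition). A config that violates it
#' (e.g. a Hann window with hop equal to the window length) is rejected
#' here rather than producing silently distorted reconstructions.
#'
#' Defaults — Hann window of 64 samples (256 ms at 250 Hz), hop 16 (75%
#' overlap), 64-point one-sided FFT — give about 3.9 Hz per frequency row,
#' covering the 2–30 Hz ERP band in roughly eight informative rows while
#' keeping the time-frequency image small enough for whole-image
#' non-local means.
#'
#' @param window_length Analysis window length in samples.
#' @param hop Frame advance in samples (`hop <= window_length`).
#' @param window_shape `"hann"` or `"hamming"`.
#' @param fft_length FFT size (`>= window_length`).
#' @param one_sided Keep only non-negative frequencies (real input).
#' @return An object of class `stft_config`.
#' @export
stft_config <- function(window_length = 64L, hop = 16L,
                        window_shape = c("hann", "hamming"),
                        fft_length = window_length, one_sided = TRUE) {
  window_shape <- match.arg(window_shape)
  window_length <- as.integer(window_length)
  hop <- as.integer(hop)
  fft_length <- as.integer(fft_length)
  if (hop < 1L || hop > window_length)
    stop("need 1 <= hop <= window_length")
  if (fft_length < window_length)
    stop("fft_length must be >= window_length")
  w <- stft_window(window_shape, window_length)
  # tiled sum of squared windows over one hop period (interior coverage)
  n_tile <- window_length * 4L
  acc <- numeric(n_tile + window_length)
  for (k in seq.int(0L, n_tile %/% hop)) {
    idx <- k * hop + seq_len(window_length)
    acc[idx] <- acc[idx] + w^2
  }
  interior <- acc[(window_length + 1L):n_tile]
  if (min(interior) < 1e-6 * max(interior))
    stop("window/hop pair violates the overlap-add condition; ",
         "exact inversion impossible")
  structure(
    list(window_length = window_length, hop = hop,
         window_shape = window_shape, fft_length = fft_length,
         one_sided = isTRUE(one_sided)),
    class = "stft_config"
  )
}

# periodic windows: COLA-friendly for hop = L/2^k
stft_window <- function(shape, n) {
  k <- seq.int(0L, n - 1L)
  switch(shape,
    hann    = 0.5 - 0.5 * cos(2 * pi * k / n),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
    stop("unknown window shape: ", shape)
  )
}

#' Short-time Fourier transform
#'
#' Transforms a 1-D signal into a complex time-frequency matrix
#' (frequencies in rows, frames in columns). The signal is zero-padded by
#' one window length at the front and as needed at the tail so that every
#' sample is covered by full window overlap; [istft()] strips the padding
#' and truncates to the original length, making the round trip exact.
#'
#' @param x Numeric vector, `length(x) >= window_length`.
#' @param config An [stft_config()].
#' @param fs Sampling rate in Hz (used only to label the axes).
#' @return An object of class `tfr`: list with complex matrix `values`,
#'   `freqs` (Hz per row), `frame_times` (s, window centre per column),
#'   `config`, `fs`, `original_length`.
#' @export
stft <- function(x, config = stft_config(), fs = 250) {
  x <- as.numeric(x)
  L <- config$window_length; H <- config$hop; NF <- config$fft_length
  if (length(x) < L)
    stop("signal shorter than one analysis window")
  n <- length(x)
  pad_front <- L
  n_frames <- ceiling((pad_front + n) / H) + (L %/% H)
  total <- (n_frames - 1L) * H + L
  xp <- c(numeric(pad_front), x, numeric(total - pad_front - n))
  w <- stft_window(config$window_shape, L)
  V <- matrix(0 + 0i, nrow = NF, ncol = n_frames)
  for (k in seq_len(n_frames)) {
    seg <- xp[((k - 1L) * H + 1L):((k - 1L) * H + L)] * w
    V[, k] <- stats::fft(c(seg, numeric(NF - L)))
  }
  if (config$one_sided) V <- V[seq_len(NF %/% 2L + 1L), , drop = FALSE]
  freqs <- (seq_len(nrow(V)) - 1L) * fs / NF
  frame_times <- ((seq_len(n_frames) - 1L) * H + L / 2 - pad_front) / fs
  structure(
    list(values = V, freqs = freqs, frame_times = frame_times,
         config = config, fs = fs, original_length = n,
         pad_front = pad_front),
    class = "tfr"
  )
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("<tfr> %d freqs x %d frames, %g-%g Hz, original length %d\n",
              nrow(x$values), ncol(x$values), min(x$freqs), max(x$freqs),
              x$original_length))
  invisible(x)
}

#' Inverse short-time Fourier transform
#'
#' Weighted overlap-add inversion: each frame spectrum is inverted,
#' windowed again by the analysis window, accumulated, and the result
#' divided by the accumulated squared window before the zero padding added
#' by [stft()] is stripped.
#'
#' @param tfr A `tfr` produced by [stft()].
#' @return Numeric vector of length `tfr$original_length`.
#' @export
istft <- function(tfr) {
  stopifnot(inherits(tfr, "tfr"))
  cfg <- tfr$config
  L <- cfg$window_length; H <- cfg$hop; NF <- cfg$fft_length
  V <- tfr$values
  if (cfg$one_sided) {
    n_half <- NF %/% 2L + 1L
    if (nrow(V) != n_half) stop("one-sided TFR has wrong number of rows")
    mirror <- Conj(V[rev(seq.int(2L, NF - n_half + 1L)), , drop = FALSE])
    V <- rbind(V, mirror)
  }
  n_frames <- ncol(V)
  total <- (n_frames - 1L) * H + L
  w <- stft_window(cfg$window_shape, L)
  acc <- numeric(total)
  wsum <- numeric(total)
  for (k in seq_len(n_frames)) {
    seg <- Re(stats::fft(V[, k], inverse = TRUE)) / NF
    idx <- ((k - 1L) * H + 1L):((k - 1L) * H + L)
    acc[idx] <- acc[idx] + seg[seq_len(L)] * w
    wsum[idx] <- wsum[idx] + w^2
  }
  out_idx <- tfr$pad_front + seq_len(tfr$original_length)
  acc[out_idx] / wsum[out_idx]
}

#' Split a complex TFR into magnitude and phase
#'
#' @param tfr A `tfr`.
#' @return List with `magnitude` (non-negative matrix) and `phase`
#'   (radians).
#' @export
split_mag_phase <- function(tfr) {
  stopifnot(inherits(tfr, "tfr"))
  list(magnitude = Mod(tfr$values), phase = Arg(tfr$values))
}

#' Recombine magnitude and phase into a TFR
#'
#' @param magnitude Non-negative real matrix.
#' @param phase Phase matrix in radians, same shape.
#' @param template A `tfr` providing axes, config and original length.
#' @return A `tfr` with values `magnitude * exp(1i * phase)`.
#' @export
combine_mag_phase <- function(magnitude, phase, template) {
  stopifnot(inherits(template, "tfr"))
  if (!all(dim(magnitude) == dim(template$values)) ||
      !all(dim(phase) == dim(template$values)))
    stop("magnitude/phase shape does not match the template TFR")
  if (any(magnitude < 0))
    stop("negative magnitudes are not allowed")
  out <- template
  out$values <- magnitude * exp(1i * phase)
  out
}

#' Export a TFR to CSV plus a JSON sidecar
#'
#' Writes `<stem>_real.csv` and `<stem>_imag.csv` (freqs x frames) and
#' `<stem>_meta.json` holding the axes and the STFT config.
#'
#' @param tfr A `tfr`.
#' @param stem Output path stem.
#' @export
tfr_export <- function(tfr, stem) {
  stopifnot(inherits(tfr, "tfr"))
  save_csv(Re(tfr$values), paste0(stem, "_real.csv"))
  save_csv(Im(tfr$values), paste0(stem, "_imag.csv"))
  meta <- list(freqs = tfr$freqs, frame_times = tfr$frame_times,
               fs = tfr$fs, original_length = tfr$original_length,
               config = unclass(tfr$config))
  jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
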