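#' Synthetic event-related potential simulation configuration
#'
#' Describes a multi-trial single-channel ERP experiment: a fixed set of
#' stimulus-locked components whose latency and amplitude jitter from
#' trial to trial, buried in structured background noise (pink 1/f EEG
#' background, a 10 Hz alpha rhythm with random phase, and band-limited
#' "EMG" activity at 30-120 Hz). The defaults mirror a rapid visual
#' target-detection block: 56 one-second trials at 250 Hz with an
#' N1-like negativity at 150 ms and a P300-like positivity at 350 ms,
#' mixed at -5 dB signal-to-noise.
#'
#' @param fs Sampling rate (Hz), default 250.
#' @param duration_s Trial length (s), default 1.
#' @param n_trials Number of trials, default 56.
#' @param components List of component descriptors, each a list with
#'   `polarity` (+1/-1), `peak_time_s`, `width_s` (Gaussian SD), and
#'   `amplitude_uv`.
#' @param latency_jitter_sd_s Trial-to-trial latency jitter SD (s),
#'   default 0.02.
#' @param amplitude_jitter_cv Trial-to-trial amplitude coefficient of
#'   variation, default 0.2.
#' @param noise List with `pink_exponent` (1/f^beta slope), `alpha_freq_hz`,
#'   `alpha_amp`, `emg_band_hz` (length-2), `emg_amp` — relative
#'   amplitudes of the three noise sources before SNR scaling.
#' @param target_snr_db Per-trial signal-to-noise ratio
#'   `10 log10(||clean||^2 / ||noise||^2)`, default -5.
#' @param n_channels 1 (default) for single-channel output; 3 adds scaled
#'   copies (gains 1.0, 0.8, 0.6) with independent noise, for testing
#'   multi-channel preprocessing.
#' @param seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(fs = 250, duration_s = 1.0, n_trials = 56L,
                       components = list(
                         list(polarity = -1, peak_time_s = 0.15,
                              width_s = 0.03, amplitude_uv = 5),
                         list(polarity = 1, peak_time_s = 0.35,
                              width_s = 0.06, amplitude_uv = 10)),
                       latency_jitter_sd_s = 0.02,
                       amplitude_jitter_cv = 0.2,
                       noise = list(pink_exponent = 1, alpha_freq_hz = 10,
                                    alpha_amp = 1, emg_band_hz = c(30, 120),
                                    emg_amp = 1),
                       target_snr_db = -5, n_channels = 1L, seed = 1L) {
  n <- fs * duration_s
  if (abs(n - round(n)) > 1e-9) stop("fs * duration_s must be an integer")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  for (cmp in components)
    if (cmp$width_s <= 0) stop("component widths must be positive")
  if (!n_channels %in% c(1L, 3L)) stop("n_channels must be 1 or 3")
  structure(
    list(fs = fs, duration_s = duration_s, n_trials = as.integer(n_trials),
         components = components,
         latency_jitter_sd_s = latency_jitter_sd_s,
         amplitude_jitter_cv = amplitude_jitter_cv, noise = noise,
         target_snr_db = target_snr_db,
         n_channels = as.integer(n_channels), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# pink 1/f^beta noise via spectral shaping of white noise, unit variance
pink_noise <- function(n, beta) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1L))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)               # symmetric shaping
  W <- W / f^(beta / 2)
  W[1L] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# band-limited white noise ("EMG"), unit variance
emg_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  high <- min(band[2L], fs / 2 * 0.99)
  bf <- signal::butter(4L, c(band[1L], high) / (fs / 2), type = "pass")
  x <- filtfilt_padded(function(z) as.numeric(signal::filtfilt(bf, z)),
                       w, pad = min(n - 1L, as.integer(round(3 * fs / band[1L]))))
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

component_waveform <- function(cmp, tt) {
  cmp$polarity * cmp$amplitude_uv *
    exp(-(tt - cmp$peak_time_s)^2 / (2 * cmp$width_s^2))
}

#' Generate a synthetic multi-trial ERP dataset
#'
#' Each trial is the sum of the configured Gaussian-windowed components —
#' with per-trial jittered latencies and amplitudes — plus structured
#' noise scaled so the realised per-trial SNR equals `target_snr_db`
#' exactly. Fully deterministic given `config$seed`; the caller's random
#' number generator state is restored on exit.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_output`: list with `trials`
#'   (n_trials x N), `clean_per_trial`, `template` (jitter-free component
#'   sum), `realized_snr_db`, `fs`, `config`; with `n_channels = 3`, also
#'   `channels`, a list of per-channel trial matrices.
#' @export
simulate_erp <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  fs <- config$fs
  n <- as.integer(round(fs * config$duration_s))
  tt <- (seq_len(n) - 1L) / fs
  template <- Reduce(`+`, lapply(config$components, component_waveform,
                                 tt = tt))
  gains <- if (config$n_channels == 3L) c(1.0, 0.8, 0.6) else 1.0
  make_noise <- function() {
    nz <- config$noise
    x <- pink_noise(n, nz$pink_exponent) +
      nz$alpha_amp * sin(2 * pi * nz$alpha_freq_hz * tt +
                           stats::runif(1L, 0, 2 * pi)) +
      nz$emg_amp * emg_noise(n, fs, nz$emg_band_hz)
    x
  }
  n_tr <- config$n_trials
  clean <- matrix(0, n_tr, n)
  channels <- lapply(gains, function(g) matrix(0, n_tr, n))
  realized <- numeric(n_tr)
  snr_lin <- 10^(config$target_snr_db / 10)
  for (i in seq_len(n_tr)) {
    tr_clean <- numeric(n)
    for (cmp in config$components) {
      cj <- cmp
      cj$peak_time_s <- cmp$peak_time_s +
        stats::rnorm(1L, sd = config$latency_jitter_sd_s)
      amp_factor <- max(0, 1 + stats::rnorm(1L, sd = config$amplitude_jitter_cv))
      cj$amplitude_uv <- cmp$amplitude_uv * amp_factor
      tr_clean <- tr_clean + component_waveform(cj, tt)
    }
    clean[i, ] <- tr_clean
    for (ch in seq_along(gains)) {
      noise <- make_noise()
      npow <- sum(noise^2)
      target_npow <- sum((gains[ch] * tr_clean)^2) / snr_lin
      if (npow > 0) noise <- noise * sqrt(target_npow / npow)
      channels[[ch]][i, ] <- gains[ch] * tr_clean + noise
      if (ch == 1L)
        realized[i] <- 10 * log10(sum(tr_clean^2) / sum(noise^2))
    }
  }
  out <- list(trials = channels[[1L]], clean_per_trial = clean,
              template = template, realized_snr_db = realized,
              fs = fs, config = config)
  if (config$n_channels == 3L) out$channels <- channels
  structure(out, class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %d trials x %d samples @ %g Hz, SNR %.1f dB (seed %d)\n",
    nrow(x$trials), ncol(x$trials), x$fs, x$config$target_snr_db,
    x$config$seed))
  invisible(x)
}

#' Across-trial average reference signal
#'
#' The pointwise mean over trials — the superposition average used as the
#' denoising ground-truth proxy.
#'
#' @param trials Numeric matrix, trials in rows.
#' @return Numeric vector of length `ncol(trials)`.
#' @export
reference_from_trials <- function(trials) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 1L) stop("no trials")
  colMeans(trials)
}
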