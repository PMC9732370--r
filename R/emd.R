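#' Ensemble EMD configuration
#'
#' @param n_ensembles Number of noise realisations to average (default
#'   100).
#' @param noise_std Standard deviation of the added white noise as a
#'   fraction of the signal's standard deviation (default 0.2).
#' @param max_imfs Maximum number of intrinsic mode functions (default 8).
#' @param sift_sd_threshold Cauchy-type sifting stop threshold
#'   (default 0.2).
#' @param seed Integer seed for the noise stream.
#' @return An object of class `eemd_config`.
#' @export
eemd_config <- function(n_ensembles = 100L, noise_std = 0.2,
                        max_imfs = 8L, sift_sd_threshold = 0.2,
                        seed = 1L) {
  if (n_ensembles < 1L) stop("n_ensembles must be >= 1")
  if (noise_std < 0) stop("noise_std must be >= 0")
  structure(
    list(n_ensembles = as.integer(n_ensembles), noise_std = noise_std,
         max_imfs = as.integer(max_imfs),
         sift_sd_threshold = sift_sd_threshold, seed = as.integer(seed)),
    class = "eemd_config"
  )
}

# strict interior local extrema of a 1-D series
local_extrema_1d <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(), min = integer()))
  i <- 2:(n - 1L)
  list(max = i[x[i] > x[i - 1L] & x[i] > x[i + 1L]],
       min = i[x[i] < x[i - 1L] & x[i] < x[i + 1L]])
}

# Natural cubic spline envelope through the given extrema, with the two
# outermost extrema reflected across each end of the series to tame the
# usual end swings. Requires >= 2 support points.
spline_envelope <- function(idx, vals, n) {
  k <- length(idx)
  # reflected abscissae are already in strictly ascending order for
  # interior extrema (2 - idx[2] < 2 - idx[1] < idx < 2n - idx[k] <
  # 2n - idx[k-1]), so no sorting or dedup is needed
  xs <- c(2 - idx[2L], 2 - idx[1L], idx,
          2 * n - idx[k], 2 * n - idx[k - 1L])
  ys <- c(vals[2L], vals[1L], vals, vals[k], vals[k - 1L])
  stats::spline(xs, ys, xout = seq_len(n), method = "natural",
                ties = list("ordered", mean))$y
}

emd_sift_once <- function(x) {
  ex <- local_extrema_1d(x)
  if (length(ex$max) < 2L || length(ex$min) < 2L) return(NULL)
  n <- length(x)
  e_up <- spline_envelope(ex$max, x[ex$max], n)
  e_lo <- spline_envelope(ex$min, x[ex$min], n)
  x - (e_up + e_lo) / 2
}

#' Empirical mode decomposition of a 1-D signal
#'
#' Standard sifting: cubic-spline envelopes through the maxima and minima,
#' subtraction of the envelope mean, and a Cauchy-type stop on the
#' normalised squared change between consecutive iterates. Modes are
#' peeled off until the residue has fewer than two maxima or minima
#' (monotone-like) or `max_imfs` is reached. Completeness is exact by
#' construction.
#'
#' @param x Numeric vector.
#' @param sd_threshold Sifting stop threshold (default 0.2).
#' @param max_imfs Maximum number of modes (default 8).
#' @param max_sift_iters Per-mode sifting cap (default 10, matching the
#'   2-D decomposition's bounded-runtime policy).
#' @return An object of class `imf_stack`: list with `imfs` (k x T
#'   matrix; zero rows when no modes) and `residue`.
#' @export
emd <- function(x, sd_threshold = 0.2, max_imfs = 8L,
                max_sift_iters = 10L) {
  x <- as.numeric(x)
  n <- length(x)
  imfs <- list()
  residue <- x
  for (k in seq_len(max_imfs)) {
    h_prev <- residue
    mode <- NULL
    for (p in seq_len(max_sift_iters)) {
      h <- emd_sift_once(h_prev)
      if (is.null(h)) {
        if (p > 1L) mode <- h_prev
        break
      }
      keep <- abs(h_prev) >= 1e-12
      sd_val <- if (any(keep))
        sum((h_prev[keep] - h[keep])^2 / h_prev[keep]^2) else 0
      if (sd_val < sd_threshold) { mode <- h; break }
      h_prev <- h
      if (p == max_sift_iters) mode <- h
    }
    if (is.null(mode)) break
    imfs[[length(imfs) + 1L]] <- mode
    residue <- residue - mode
  }
  imf_mat <- if (length(imfs)) do.call(rbind, imfs)
             else matrix(numeric(), 0L, n)
  structure(list(imfs = imf_mat, residue = residue), class = "imf_stack")
}

#' Ensemble empirical mode decomposition
#'
#' Averages the modes of `n_ensembles` decompositions of the signal with
#' independent white Gaussian noise added (standard deviation
#' `noise_std * sd(x)`), aligning modes by index and zero-padding shorter
#' decompositions. The noise stream is fully determined by `config$seed`,
#' and the caller's random number generator state is left untouched.
#'
#' @param x Numeric vector.
#' @param config An [eemd_config()].
#' @return An `imf_stack` of ensemble-mean modes and residue.
#' @export
eemd <- function(x, config = eemd_config()) {
  x <- as.numeric(x)
  n <- length(x)
  if (config$noise_std == 0 || config$n_ensembles == 1L && config$noise_std == 0)
    return(emd(x, config$sift_sd_threshold, config$max_imfs))
  sigma <- config$noise_std * stats::sd(x)
  if (!is.finite(sigma) || sigma == 0)
    return(emd(x, config$sift_sd_threshold, config$max_imfs))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  acc_imfs <- matrix(0, config$max_imfs, n)
  acc_res <- numeric(n)
  max_k <- 0L
  for (j in seq_len(config$n_ensembles)) {
    xj <- x + stats::rnorm(n, sd = sigma)
    dj <- emd(xj, config$sift_sd_threshold, config$max_imfs)
    k <- nrow(dj$imfs)
    if (k > 0L) acc_imfs[seq_len(k), ] <-
      acc_imfs[seq_len(k), , drop = FALSE] + dj$imfs
    acc_res <- acc_res + dj$residue
    max_k <- max(max_k, k)
  }
  imfs <- acc_imfs[seq_len(max_k), , drop = FALSE] / config$n_ensembles
  structure(list(imfs = imfs, residue = acc_res / config$n_ensembles),
            class = "imf_stack")
}
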