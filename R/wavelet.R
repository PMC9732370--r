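# Orthonormal Daubechies-4 (8-tap) scaling filter; the wavelet filter is
# its alternating-sign reverse (quadrature mirror pair).
db4_filters <- function() {
  h <- c(0.23037781330885523, 0.71484657055254153, 0.63088076792959036,
         -0.02798376941698385, -0.18703481171888114, 0.03084138183598697,
         0.03288301166698295, -0.01059740178499728)
  L <- length(h)
  g <- (-1)^(seq_len(L) - 1L) * rev(h)
  list(h = h, g = g)
}

# one level of the periodised discrete wavelet transform (n even)
dwt_step <- function(x, h, g) {
  n <- length(x); L <- length(h)
  half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    a[k] <- sum(h * x[idx])
    d[k] <- sum(g * x[idx])
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, g) {
  half <- length(a); n <- 2L * half; L <- length(h)
  x <- numeric(n)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    x[idx] <- x[idx] + h * a[k] + g * d[k]
  }
  x
}

# full periodised DWT of a power-of-two-length signal
dwt <- function(x, levels) {
  f <- db4_filters()
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, f$h, f$g)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt <- function(coeffs) {
  f <- db4_filters()
  a <- coeffs$approx
  for (l in rev(seq_along(coeffs$details)))
    a <- idwt_step(a, coeffs$details[[l]], f$h, f$g)
  a
}

#' Wavelet soft-threshold denoising
#'
#' Discrete wavelet transform (Daubechies-4, periodised; the signal is
#' zero-padded to the next power of two and the result truncated back),
#' universal threshold `sqrt(2 log N) * sigma` with `sigma` estimated as
#' `median(|d1|) / 0.6745` from the finest detail coefficients, soft
#' thresholding of all detail levels, inverse transform.
#'
#' @param x Numeric vector, length >= 8.
#' @param levels Decomposition depth; default `floor(log2(N)) - 2`,
#'   at least 1.
#' @return Denoised signal, same length as `x`.
#' @export
wavelet_threshold_denoise <- function(x, levels = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("signal too short for wavelet denoising (need >= 8)")
  if (is.null(levels)) levels <- max(1L, floor(log2(n)) - 2L)
  n_pad <- 2L^ceiling(log2(n))
  levels <- min(levels, floor(log2(n_pad)) - 1L)
  xp <- c(x, numeric(n_pad - n))
  cf <- dwt(xp, levels)
  d1 <- cf$details[[1L]]
  sigma <- stats::median(abs(d1)) / 0.6745
  thr <- sqrt(2 * log(n)) * sigma
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  cf$details <- lapply(cf$details, soft)
  y <- idwt(cf)
  y[seq_len(n)]
}
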