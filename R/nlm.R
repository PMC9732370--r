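#' Non-local means configuration
#'
#' @param patch_radius Patch radius in pixels; the comparison patch is
#'   `(2r+1) x (2r+1)` (default 2, i.e. 5x5).
#' @param search_radius Search radius in pixels, or `Inf` for the whole
#'   image (the default: time-frequency images here are small, and the
#'   energy density at one time is informative about every other time).
#' @param h Attenuation coefficient of the exponential similarity kernel,
#'   in intensity units. `NULL` (default) selects `h = h_factor * sigma`
#'   per image, where `sigma` is the robust gradient-based noise estimate
#'   of [estimate_noise_sd()]; this makes the filter scale-free across
#'   mode images of very different amplitudes.
#' @param h_factor Multiplier for the automatic `h` (default 0.6).
#' @param a Standard deviation (pixels) of the Gaussian weighting applied
#'   to the patch distance (default 1).
#' @return An object of class `nlm_config`.
#' @export
nlm_config <- function(patch_radius = 2L, search_radius = Inf,
                       h = NULL, h_factor = 0.6, a = 1) {
  if (patch_radius < 1L) stop("patch_radius must be >= 1")
  if (!is.null(h) && h <= 0) stop("h must be positive")
  if (a <= 0) stop("a must be positive")
  if (h_factor <= 0) stop("h_factor must be positive")
  structure(
    list(patch_radius = as.integer(patch_radius),
         search_radius = search_radius, h = h, h_factor = h_factor, a = a),
    class = "nlm_config"
  )
}

#' Robust noise standard deviation of an image
#'
#' Median absolute first difference (pooled over both axes) divided by
#' 0.6745, the Gaussian consistency constant for median absolute
#' deviations.
#'
#' @param img Numeric matrix.
#' @return Non-negative scalar estimate.
#' @export
estimate_noise_sd <- function(img) {
  d <- c(abs(diff(img)), abs(t(diff(t(img)))))
  if (!length(d)) return(0)
  stats::median(d) / 0.6745
}

# Normalised Gaussian kernel over patch offsets, sd = a pixels.
patch_kernel <- function(patch_radius, a) {
  off <- seq.int(-patch_radius, patch_radius)
  g1 <- exp(-off^2 / (2 * a^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# Mirror-pad an image by `r` pixels (reflection without repeating edges)
# and return the matrix of patch vectors: one row per image pixel
# (column-major order), one column per patch offset.
patch_matrix <- function(img, patch_radius) {
  nr <- nrow(img); nc <- ncol(img); r <- patch_radius
  ridx <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  cidx <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  P <- img[ridx, cidx, drop = FALSE]
  side <- 2L * r + 1L
  out <- matrix(0, nr * nc, side * side)
  k <- 0L
  for (dc in seq_len(side)) for (dr in seq_len(side)) {
    k <- k + 1L
    out[, k] <- as.numeric(P[(dr):(dr + nr - 1L), (dc):(dc + nc - 1L)])
  }
  out
}

resolve_h <- function(img, config) {
  h <- config$h
  if (is.null(h)) {
    sigma <- estimate_noise_sd(img)
    h <- config$h_factor * sigma
  }
  if (h <= 0) h <- 1  # flat image: distances are all zero anyway
  h
}

#' Gaussian-weighted squared patch distance between two pixels
#'
#' `d(i, j) = sum_k G_a(k) * (N(i)_k - N(j)_k)^2` over patch offsets `k`,
#' with `G_a` a normalised discrete Gaussian and patches mirror-padded at
#' the borders.
#'
#' @param img Numeric matrix.
#' @param i,j Pixel coordinates as `c(row, col)` (1-based).
#' @param config An [nlm_config()].
#' @return Non-negative scalar.
#' @export
patch_distance <- function(img, i, j, config = nlm_config()) {
  r <- config$patch_radius
  g <- as.numeric(patch_kernel(r, config$a))
  pm <- patch_matrix(img, r)
  nr <- nrow(img)
  pi_ <- (i[2L] - 1L) * nr + i[1L]
  pj <- (j[2L] - 1L) * nr + j[1L]
  sum(g * (pm[pi_, ] - pm[pj, ])^2)
}

#' Similarity weights of one pixel against its search region
#'
#' `w(i, j) = exp(-d(i, j) / h^2) / c(i)` with `c(i)` normalising the
#' weights to sum to one over the search region. The pixel itself is
#' included with its natural weight (`d = 0`).
#'
#' @param img Numeric matrix.
#' @param i Pixel coordinate `c(row, col)`.
#' @param config An [nlm_config()].
#' @return Numeric matrix of weights over the search region (same shape as
#'   `img` for full-image search, with zeros outside the search window
#'   otherwise); weights sum to 1.
#' @export
weights_for_pixel <- function(img, i, config = nlm_config()) {
  r <- config$patch_radius
  h <- resolve_h(img, config)
  g <- as.numeric(patch_kernel(r, config$a))
  pm <- patch_matrix(img, r)
  nr <- nrow(img); nc <- ncol(img)
  pi_ <- (i[2L] - 1L) * nr + i[1L]
  d <- colSums(g * (t(pm) - pm[pi_, ])^2)
  w <- exp(-d / h^2)
  W <- matrix(w, nr, nc)
  if (is.finite(config$search_radius)) {
    sr <- config$search_radius
    mask <- matrix(FALSE, nr, nc)
    rows <- max(1L, i[1L] - sr):min(nr, i[1L] + sr)
    cols <- max(1L, i[2L] - sr):min(nc, i[2L] + sr)
    mask[rows, cols] <- TRUE
    W[!mask] <- 0
  }
  W / sum(W)
}

#' Non-local means denoising of an image
#'
#' Replaces every pixel by the similarity-weighted average of the pixels
#' in its search region (by default the whole image), with patch
#' similarity measured by the Gaussian-weighted squared distance between
#' mirror-padded neighbourhoods. The output is a convex combination of
#' input pixels, hence bounded by the input range.
#'
#' @param img Finite numeric matrix.
#' @param config An [nlm_config()].
#' @return Denoised matrix, same shape.
#' @export
nlm_denoise <- function(img, config = nlm_config()) {
  img <- as.matrix(img)
  if (any(!is.finite(img))) stop("image contains non-finite values")
  nr <- nrow(img); nc <- ncol(img); n <- nr * nc
  r <- config$patch_radius
  h <- resolve_h(img, config)
  g <- patch_kernel(r, config$a)
  pm <- patch_matrix(img, r) * rep(sqrt(as.numeric(g)), each = n)
  # pairwise Gaussian-weighted squared distances via the Gram matrix
  sq <- rowSums(pm^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(pm)
  D[D < 0] <- 0
  diag(D) <- 0  # d(i, i) is exactly zero by definition; the Gram-based
                # evaluation leaves rounding residue that matters when h
                # is tiny (near-constant images)
  W <- exp(-D / h^2)
  if (is.finite(config$search_radius)) {
    sr <- config$search_radius
    rows <- rep(seq_len(nr), times = nc)
    cols <- rep(seq_len(nc), each = nr)
    keep <- abs(outer(rows, rows, "-")) <= sr &
            abs(outer(cols, cols, "-")) <= sr
    W[!keep] <- 0
  }
  out <- (W %*% as.numeric(img)) / rowSums(W)
  matrix(out, nr, nc)
}
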