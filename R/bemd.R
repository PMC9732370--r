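#' Bidimensional empirical mode decomposition configuration
#'
#' @param n_bimfs Maximum number of intrinsic mode images to extract
#'   (default 5: in practice the fifth mode of an ERP spectrogram carries
#'   almost no oscillatory content and behaves like a residue).
#' @param sd_threshold Sifting stop threshold on the normalised squared
#'   difference between consecutive sift iterates (default 0.25).
#' @param max_sift_iters Hard cap on sift iterations per mode (default 10),
#'   bounding runtime when the threshold is slow to reach.
#' @return An object of class `bemd_config`.
#' @export
bemd_config <- function(n_bimfs = 5L, sd_threshold = 0.25,
                        max_sift_iters = 10L) {
  if (n_bimfs < 1L) stop("n_bimfs must be >= 1")
  if (sd_threshold <= 0) stop("sd_threshold must be positive")
  if (max_sift_iters < 1L) stop("max_sift_iters must be >= 1")
  structure(
    list(n_bimfs = as.integer(n_bimfs), sd_threshold = sd_threshold,
         max_sift_iters = as.integer(max_sift_iters),
         neighborhood = "8-connected", boundary = "mirror"),
    class = "bemd_config"
  )
}

#' Find strict local extrema of a matrix
#'
#' A pixel is a maximum iff strictly greater than all eight neighbours,
#' with borders mirror-extended (reflection without repeating the edge),
#' so border pixels can qualify when they dominate their interior
#' neighbours. Plateaus yield no extremum. Minima are symmetric.
#'
#' @param m Numeric matrix, at least 3x3.
#' @return List with `maxima` and `minima`, each a list of `rows`, `cols`
#'   (1-based) and `values`.
#' @export
find_extrema <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) stop("matrix must be at least 3x3")
  # mirror extension by one pixel: pad row 0 = row 2, pad row nr+1 = row nr-1
  P <- matrix(0, nr + 2L, nc + 2L)
  P[2:(nr + 1L), 2:(nc + 1L)] <- m
  P[1L, 2:(nc + 1L)] <- m[2L, ]; P[nr + 2L, 2:(nc + 1L)] <- m[nr - 1L, ]
  P[, 1L] <- P[, 3L]; P[, nc + 2L] <- P[, nc]
  ctr <- P[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- matrix(TRUE, nr, nc); is_min <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- P[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    is_max <- is_max & (ctr > nb)
    is_min <- is_min & (ctr < nb)
  }
  pick <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    list(rows = unname(idx[, 1L]), cols = unname(idx[, 2L]),
         values = m[idx])
  }
  list(maxima = pick(is_max), minima = pick(is_min))
}

# Reflect scattered support points across the four image borders so the
# fitted envelope is constrained beyond the extrema hull (standard BEMD
# boundary mitigation).
mirror_pad_points <- function(rows, cols, values, nr, nc) {
  r <- c(rows, 1 - rows, 2 * nr + 1 - rows, rows, rows)
  c_ <- c(cols, cols, cols, 1 - cols, 2 * nc + 1 - cols)
  v <- rep(values, 5L)
  keep <- !duplicated(cbind(r, c_))
  list(rows = r[keep], cols = c_[keep], values = v[keep])
}

#' Fit a smooth envelope surface through scattered support points
#'
#' Thin-plate spline interpolation (the smooth bivariate analogue of the
#' cubic spline) through the support points, evaluated on the full
#' `shape[1] x shape[2]` grid. With fewer than 16 points, or when the
#' spline system is singular (degenerate point configurations), the fit
#' falls back to a least-squares plane, and to a constant when even a
#' plane is under-determined.
#'
#' @param rows,cols Support point coordinates (may lie outside the grid,
#'   e.g. mirror-padded points).
#' @param values Support values.
#' @param shape `c(n_rows, n_cols)` of the output grid.
#' @return Numeric matrix of the fitted surface.
#' @export
envelope_surface <- function(rows, cols, values, shape) {
  n <- length(values)
  if (n == 0L) stop("no extrema: cannot fit an envelope surface")
  if (length(rows) != n || length(cols) != n)
    stop("rows/cols/values lengths differ")
  nr <- shape[1L]; nc <- shape[2L]
  grid <- cbind(rep(seq_len(nr), times = nc), rep(seq_len(nc), each = nr))
  fit <- NULL
  if (n >= 16L) fit <- tps_fit(rows, cols, values)
  if (!is.null(fit)) {
    # near-singular systems can return finite but absurd coefficients;
    # accept the spline only if it actually interpolates its support
    at_support <- tps_eval(fit, rows, cols)
    vrange <- max(diff(range(values)), 1e-12)
    if (max(abs(at_support - values)) > 1e-6 * vrange) fit <- NULL
  }
  if (!is.null(fit)) {
    z <- tps_eval(fit, grid[, 1L], grid[, 2L])
    if (any(!is.finite(z))) z <- plane_eval(rows, cols, values, grid)
  } else {
    z <- plane_eval(rows, cols, values, grid)
  }
  matrix(z, nr, nc)
}

# Thin-plate spline system: kernel U(r) = r^2 log r, affine polynomial part.
# Returns NULL when the system is singular.
tps_fit <- function(rows, cols, values) {
  n <- length(values)
  dx <- outer(rows, rows, "-"); dy <- outer(cols, cols, "-")
  r2 <- dx * dx + dy * dy
  K <- matrix(0, n, n)
  nz <- r2 > 0
  K[nz] <- 0.5 * r2[nz] * log(r2[nz])
  P <- cbind(1, rows, cols)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  sol <- tryCatch(solve(A, c(values, numeric(3L))),
                  error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(NULL)
  list(rows = rows, cols = cols, w = sol[seq_len(n)],
       a = sol[(n + 1L):(n + 3L)])
}

tps_eval <- function(fit, qr_, qc) {
  dx <- outer(qr_, fit$rows, "-"); dy <- outer(qc, fit$cols, "-")
  r2 <- dx * dx + dy * dy
  U <- matrix(0, nrow(r2), ncol(r2))
  nz <- r2 > 0
  U[nz] <- 0.5 * r2[nz] * log(r2[nz])
  as.numeric(U %*% fit$w + fit$a[1L] + fit$a[2L] * qr_ + fit$a[3L] * qc)
}

plane_eval <- function(rows, cols, values, grid) {
  X <- cbind(1, rows, cols)
  beta <- tryCatch(qr.coef(qr(X), values), error = function(e) NULL)
  if (is.null(beta) || any(is.na(beta)))
    return(rep(mean(values), nrow(grid)))
  beta[1L] + beta[2L] * grid[, 1L] + beta[3L] * grid[, 2L]
}

#' One sifting step of 2-D empirical mode decomposition
#'
#' Detects extrema, fits upper and lower envelope surfaces (support points
#' mirror-reflected across the borders before fitting), and subtracts the
#' envelope mean.
#'
#' @param m Numeric matrix.
#' @return List with `h = m - envelope_mean` and `envelope_mean`, or
#'   `NULL` when the matrix has no maxima or no minima (monotone residue).
#' @export
sift_once <- function(m) {
  ex <- find_extrema(m)
  if (length(ex$maxima$values) == 0L || length(ex$minima$values) == 0L)
    return(NULL)
  sh <- dim(m)
  up <- ex$maxima; lo <- ex$minima
  up <- mirror_pad_points(up$rows, up$cols, up$values, sh[1L], sh[2L])
  lo <- mirror_pad_points(lo$rows, lo$cols, lo$values, sh[1L], sh[2L])
  e_max <- envelope_surface(up$rows, up$cols, up$values, sh)
  e_min <- envelope_surface(lo$rows, lo$cols, lo$values, sh)
  em <- (e_max + e_min) / 2
  list(h = m - em, envelope_mean = em)
}

# Normalised squared difference between consecutive sift iterates, summed
# over the field; cells with |h_prev| below 1e-12 are excluded because the
# criterion divides by h_prev^2.
sift_sd <- function(h_prev, h) {
  keep <- abs(h_prev) >= 1e-12
  if (!any(keep)) return(0)
  sum((h_prev[keep] - h[keep])^2 / h_prev[keep]^2)
}

#' Extract one bidimensional intrinsic mode function
#'
#' Repeats [sift_once()] on successive iterates until the normalised
#' squared difference between consecutive iterates falls below
#' `config$sd_threshold`, or `config$max_sift_iters` is reached.
#'
#' @param m Numeric matrix with at least one maximum and one minimum.
#' @param config A [bemd_config()].
#' @return List with `bimf` and `n_iters`, or `NULL` on a monotone input.
#' @export
extract_bimf <- function(m, config = bemd_config()) {
  h_prev <- m
  for (p in seq_len(config$max_sift_iters)) {
    s <- sift_once(h_prev)
    if (is.null(s)) {
      if (p == 1L) return(NULL)           # monotone from the start
      return(list(bimf = h_prev, n_iters = p - 1L))
    }
    h <- s$h
    if (sift_sd(h_prev, h) < config$sd_threshold)
      return(list(bimf = h, n_iters = p))
    h_prev <- h
  }
  list(bimf = h_prev, n_iters = config$max_sift_iters)
}

#' Bidimensional empirical mode decomposition
#'
#' Decomposes a real matrix into an ordered stack of bidimensional
#' intrinsic mode functions (highest to lowest spatial frequency) plus a
#' residue. Modes are peeled off the running residue until `n_bimfs` have
#' been extracted or the residue has no extrema left. The decomposition is
#' complete by construction: `Reduce("+", bimfs) + residue` reproduces the
#' input exactly.
#'
#' @param m Finite numeric matrix, at least 3x3.
#' @param config A [bemd_config()].
#' @return An object of class `bimf_set`: list with `bimfs` (list of
#'   matrices), `residue`, `sift_counts`.
#' @export
bemd <- function(m, config = bemd_config()) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("input matrix contains non-finite values")
  bimfs <- list(); counts <- integer()
  residue <- m
  for (i in seq_len(config$n_bimfs)) {
    res <- extract_bimf(residue, config)
    if (is.null(res)) break
    bimfs[[length(bimfs) + 1L]] <- res$bimf
    counts <- c(counts, res$n_iters)
    residue <- residue - res$bimf
  }
  structure(
    list(bimfs = bimfs, residue = residue, sift_counts = counts),
    class = "bimf_set"
  )
}

#' @export
print.bimf_set <- function(x, ...) {
  cat(sprintf("<bimf_set> %d BIMFs + residue (%d x %d), sift counts: %s\n",
              length(x$bimfs), nrow(x$residue), ncol(x$residue),
              paste(x$sift_counts, collapse = ", ")))
  invisible(x)
}
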