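# shared fixtures: deterministic test signals and the literal nested-loop
# transcription of the non-local means equations used as an oracle

sinusoid <- function(freq, fs, n, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (seq_len(n) - 1) / fs + phase)
}

seeded_matrix <- function(seed, nr, nc = nr, sd = 1) {
  set.seed(seed)
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

seeded_vector <- function(seed, n, sd = 1) {
  set.seed(seed)
  rnorm(n, sd = sd)
}

# amplitude of a (roughly sinusoidal) series over its central half
central_amplitude <- function(x) {
  n <- length(x)
  mid <- x[floor(n / 4):ceiling(3 * n / 4)]
  (max(mid) - min(mid)) / 2
}

# Literal pixel-by-pixel transcription of the non-local means weighting:
# Gaussian-weighted squared patch distance, exponential weights normalised
# per pixel, weighted average over the whole image. Written independently
# of the package's vectorised implementation.
nlm_oracle <- function(F, patch_radius = 2L, a = 1, h = NULL,
                       h_factor = 0.6) {
  nr <- nrow(F); nc <- ncol(F); r <- patch_radius
  if (is.null(h)) {
    diffs <- c(abs(diff(F)), abs(t(diff(t(F)))))
    h <- h_factor * (median(diffs) / 0.6745)
    if (h <= 0) h <- 1
  }
  off <- -r:r
  g1 <- exp(-off^2 / (2 * a^2))
  G <- outer(g1, g1)
  G <- G / sum(G)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    ifelse(i > n, 2L * n - i, i)
  }
  get_patch <- function(i, j) {
    out <- matrix(0, 2 * r + 1, 2 * r + 1)
    for (aa in 1:(2 * r + 1)) for (bb in 1:(2 * r + 1))
      out[aa, bb] <- F[refl(i + aa - r - 1L, nr), refl(j + bb - r - 1L, nc)]
    out
  }
  # extract each pixel's neighbourhood once, then apply the weighting
  # formulas pixel pair by pixel pair
  patches <- vector("list", nr * nc)
  for (i in 1:nr) for (j in 1:nc)
    patches[[(j - 1L) * nr + i]] <- get_patch(i, j)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    Ni <- patches[[(j - 1L) * nr + i]]
    wsum <- 0; acc <- 0
    for (p in 1:nr) for (q in 1:nc) {
      d <- sum(G * (Ni - patches[[(q - 1L) * nr + p]])^2)
      w <- exp(-d / h^2)
      wsum <- wsum + w
      acc <- acc + w * F[p, q]
    }
    out[i, j] <- acc / wsum
  }
  out
}
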