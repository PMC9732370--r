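sawtooth <- function(freq, fs, n) {
  t <- (seq_len(n) - 1) / fs
  2 * (freq * t - floor(freq * t)) - 1
}

test_that("FastICA recovers two mixed sources up to sign/permutation", {
  fs <- 250; n <- 500
  S <- rbind(sawtooth(7, fs, n), sinusoid(11, fs, n))
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  for (seed in 1:5) {
    ica <- fastica(A %*% S, n_components = 2L, seed = seed)
    cm <- abs(cor(t(ica$sources), t(S)))
    expect_gt(min(apply(cm, 2, max)), 0.95)
    expect_lt(max(abs(apply(ica$sources, 1, var) - 1)), 1e-6)
  }
})

test_that("FastICA rejects rank-deficient input", {
  s <- sinusoid(11, 250, 400)
  X <- rbind(s, 2 * s)
  expect_error(fastica(X, n_components = 2L), "rank")
})

test_that("CCA of a set with itself has correlation 1", {
  X <- seeded_matrix(3, 3, 400)
  cc <- cca_first_variate(X, X)
  expect_lt(abs(cc$rho - 1), 1e-10)
})

test_that("CCA rho equals the Pearson correlation of its variates", {
  X1 <- seeded_matrix(4, 3, 400)
  X2 <- seeded_matrix(5, 3, 400)
  cc <- cca_first_variate(X1, X2)
  v1 <- as.numeric(t(cc$w1) %*% (X1 - rowMeans(X1)))
  v2 <- as.numeric(t(cc$w2) %*% (X2 - rowMeans(X2)))
  # the generalized-eigenproblem singular value agrees with the empirical
  # correlation of the variates it defines
  expect_lt(abs(cc$rhos[1] - abs(cor(v1, v2))), 1e-8)
  expect_equal(cc$rho, abs(cor(v1, v2)))
  expect_true(all(diff(cc$rhos) <= 1e-12))
})

test_that("CCA eigen solution dominates a random-projection search", {
  X1 <- seeded_matrix(6, 3, 300)
  X2 <- seeded_matrix(7, 3, 300)
  cc <- cca_first_variate(X1, X2)
  set.seed(8)
  best <- 0
  for (k in seq_len(20000)) {
    w1 <- rnorm(3); w2 <- rnorm(3)
    r <- abs(cor(as.numeric(w1 %*% X1), as.numeric(w2 %*% X2)))
    if (r > best) best <- r
  }
  expect_gte(cc$rho, best - 1e-3)
})

test_that("EEMD-ICA returns the source closest to the reference", {
  sim <- simulate_erp(sim_config(seed = 1, n_trials = 8))
  ref <- reference_from_trials(sim$trials)
  trial <- sim$trials[1, ]
  cfg <- eemd_config(n_ensembles = 10L)
  out1 <- eemd_ica_denoise(trial, ref, cfg)
  out2 <- eemd_ica_denoise(trial, ref, cfg)
  expect_identical(out1, out2)                  # deterministic
  expect_length(out1, length(trial))
  # the returned component is the argmax over sources by |corr| with ref
  X <- rbind(eemd(trial, cfg)$imfs, eemd(trial, cfg)$residue)
  sds <- apply(X, 1, sd)
  X <- X[sds > 1e-10 * max(sds), ]
  ica <- suppressWarnings(
    fastica(X, n_components = min(nrow(X), 8L), seed = 1L,
            on_nonconvergence = "warn"))
  cors <- abs(apply(ica$sources, 1, cor, y = ref))
  expect_equal(abs(cor(out1, ref)), max(cors), tolerance = 1e-6)
  expect_error(eemd_ica_denoise(trial, ref[-1], cfg), "length")
})

test_that("EEMD-CCA output is aligned, rescaled and deterministic", {
  sim <- simulate_erp(sim_config(seed = 2, n_trials = 4))
  trial <- sim$trials[1, ]
  cfg <- eemd_config(n_ensembles = 10L)
  out1 <- eemd_cca_denoise(trial, cfg)
  expect_length(out1, length(trial))
  expect_identical(out1, eemd_cca_denoise(trial, cfg))
  expect_error(eemd_cca_denoise(c(1, 2), cfg), "short")
})
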