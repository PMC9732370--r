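test_that("extrema detection finds strict 8-neighbour extrema", {
  expect_error(find_extrema(matrix(1, 2, 2)), "3x3")
  cst <- find_extrema(matrix(1, 5, 5))
  expect_length(cst$maxima$values, 0)
  expect_length(cst$minima$values, 0)

  spike <- matrix(0, 5, 5); spike[3, 3] <- 1
  ex <- find_extrema(spike)
  expect_equal(cbind(ex$maxima$rows, ex$maxima$cols),
               cbind(3L, 3L), ignore_attr = TRUE)

  m <- seeded_matrix(4, 9)
  exm <- find_extrema(m)
  exn <- find_extrema(-m)
  expect_equal(exm$maxima$rows, exn$minima$rows)
  expect_equal(exm$maxima$cols, exn$minima$cols)
  expect_equal(exm$maxima$values, -exn$minima$values)
  expect_equal(exm$minima$rows, exn$maxima$rows)
})

test_that("plateaus produce no extremum", {
  m <- matrix(0, 5, 5)
  m[2:3, 3] <- 1  # two-pixel plateau at the top
  ex <- find_extrema(m)
  expect_length(ex$maxima$values, 0)
})

test_that("envelope surfaces interpolate their support", {
  # constant support -> constant surface
  set.seed(5)
  rows <- sample(1:12, 20, replace = TRUE)
  cols <- sample(1:12, 20, replace = TRUE)
  keep <- !duplicated(cbind(rows, cols))
  rows <- rows[keep]; cols <- cols[keep]
  s <- envelope_surface(rows, cols, rep(3.5, length(rows)), c(12L, 12L))
  expect_lt(max(abs(s - 3.5)), 1e-6)

  # scattered values are interpolated at the support points
  vals <- rnorm(length(rows))
  s2 <- envelope_surface(rows, cols, vals, c(12L, 12L))
  expect_lt(max(abs(s2[cbind(rows, cols)] - vals)), 1e-6)

  # 4 corner points of the plane z = x + y recover the plane
  nr <- 8L
  pr <- c(1L, 1L, nr, nr); pc <- c(1L, nr, 1L, nr)
  s3 <- envelope_surface(pr, pc, pr + pc, c(nr, nr))
  truth <- outer(seq_len(nr), seq_len(nr), `+`)
  expect_lt(max(abs(s3 - truth)), 1e-6)

  expect_error(envelope_surface(integer(), integer(), numeric(), c(5L, 5L)),
               "no extrema")
})

test_that("one sift removes most of a symmetric oscillation's local mean", {
  g <- seq_len(64)
  m <- outer(sin(2 * pi * g / 8), sin(2 * pi * g / 8))
  s <- sift_once(m)
  expect_lt(sqrt(sum(s$envelope_mean^2)) / sqrt(sum(m^2)), 0.2)
  sn <- sift_once(-m)
  expect_equal(sn$h, -s$h)
  expect_null(sift_once(matrix(2, 6, 6)))
})

test_that("sifting stops by threshold or iteration cap", {
  cfg <- bemd_config(max_sift_iters = 4L)
  m <- seeded_matrix(8, 24)
  res <- extract_bimf(m, cfg)
  expect_lte(res$n_iters, 4L)
  # an input already satisfying the criterion after one sift stops at 1
  res2 <- extract_bimf(m, bemd_config(sd_threshold = 1e9))
  expect_equal(res2$n_iters, 1L)
  expect_null(extract_bimf(matrix(1, 5, 5), cfg))
})

test_that("default sifting threshold is 0.25 and mode count is 5", {
  cfg <- bemd_config()
  expect_equal(cfg$sd_threshold, 0.25)
  expect_equal(cfg$n_bimfs, 5L)
})

test_that("decomposition is complete and separates scales", {
  m <- seeded_matrix(17, 32)
  d <- bemd(m, bemd_config())
  recon <- Reduce(`+`, d$bimfs) + d$residue
  expect_lt(max(abs(recon - m)), 1e-8)

  dc <- bemd(matrix(4, 8, 8))
  expect_length(dc$bimfs, 0)
  expect_equal(dc$residue, matrix(4, 8, 8))
  expect_error(bemd(matrix(c(NA, 1:8), 3, 3)), "non-finite")

  # fast oscillation + plane split into first mode and residue
  g <- seq_len(48)
  osc <- outer(sin(2 * pi * g / 6), cos(2 * pi * g / 6))
  plane <- outer(g / 24, g / 24, `+`)
  d2 <- bemd(osc + plane, bemd_config(n_bimfs = 3L))
  expect_gt(abs(cor(as.numeric(d2$bimfs[[1]]), as.numeric(osc))), 0.8)
  expect_gt(abs(cor(as.numeric(d2$residue), as.numeric(plane))), 0.8)
})

test_that("modes are ordered from fine to coarse spatial scale", {
  grad_mag <- function(m) mean(abs(diff(m))) + mean(abs(t(diff(t(m)))))
  violations <- 0L
  for (seed in 1:20) {
    m <- seeded_matrix(seed + 300, 24)
    sm <- nlm_denoise(m, nlm_config(h = 2))  # band-limit a little
    d <- bemd(sm, bemd_config(n_bimfs = 3L))
    g <- vapply(d$bimfs, grad_mag, numeric(1))
    violations <- violations + sum(diff(g) > 0)
  }
  expect_lte(violations, 2L)
})

test_that("decomposing -M yields the negated modes of M exactly", {
  m <- seeded_matrix(23, 24)
  d <- bemd(m); dn <- bemd(-m)
  expect_equal(length(d$bimfs), length(dn$bimfs))
  for (i in seq_along(d$bimfs))
    expect_identical(dn$bimfs[[i]], -d$bimfs[[i]])
  expect_identical(dn$residue, -d$residue)
})
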