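test_that("patch distances are symmetric, zero on identity and on flats", {
  img <- seeded_matrix(1, 12)
  cfg <- nlm_config()
  expect_equal(patch_distance(img, c(4, 5), c(4, 5), cfg), 0)
  d_ij <- patch_distance(img, c(2, 3), c(9, 10), cfg)
  d_ji <- patch_distance(img, c(9, 10), c(2, 3), cfg)
  expect_equal(d_ij, d_ji)
  expect_gte(d_ij, 0)
  flat <- matrix(2, 10, 10)
  expect_equal(patch_distance(flat, c(2, 2), c(8, 5), cfg), 0)
})

test_that("weights are a proper convex combination", {
  cfg <- nlm_config()
  flat <- matrix(1, 9, 9)
  w <- weights_for_pixel(flat, c(5, 5), cfg)
  expect_equal(max(abs(w - 1 / 81)), 0)
  for (seed in 1:3) {
    img <- seeded_matrix(seed, 11)
    w <- weights_for_pixel(img, c(3, 7), cfg)
    expect_true(all(w >= 0))
    expect_lt(abs(sum(w) - 1), 1e-12)
  }
  # h -> infinity flattens the weights
  img <- seeded_matrix(4, 11)
  w_inf <- weights_for_pixel(img, c(6, 6),
                             nlm_config(h = 1e6 * diff(range(img))))
  expect_lt(max(abs(w_inf - 1 / length(img))), 1e-6)
})

test_that("denoising matches the literal nested-loop transcription", {
  for (seed in 1:10) {
    img <- seeded_matrix(seed, 16)
    fast <- nlm_denoise(img, nlm_config())
    slow <- nlm_oracle(img)
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
})

test_that("output is bounded by the input range and preserves flats", {
  flat <- matrix(3.25, 12, 12)
  expect_equal(nlm_denoise(flat, nlm_config()), flat)
  for (seed in 11:15) {
    img <- seeded_matrix(seed, 14)
    out <- nlm_denoise(img, nlm_config())
    expect_gte(min(out), min(img))
    expect_lte(max(out), max(img))
  }
  expect_error(nlm_denoise(matrix(c(Inf, 1:8), 3, 3)), "non-finite")
})

test_that("i.i.d. Gaussian noise variance is reduced", {
  for (seed in 1:20) {
    img <- seeded_matrix(seed + 50, 16)
    out <- nlm_denoise(img, nlm_config())
    expect_lt(var(as.numeric(out)), var(as.numeric(img)))
  }
})

test_that("the filter is translation-equivariant away from borders", {
  # two crops of the same scene shifted by two rows: with a fixed h and a
  # finite search window, interior pixels whose full dependency region
  # (search radius + patch radius) lies inside both crops must agree
  M <- seeded_matrix(33, 26, 16)
  crop_a <- M[1:20, ]
  crop_b <- M[3:22, ]
  cfg <- nlm_config(search_radius = 3L, h = 0.8)
  out_a <- nlm_denoise(crop_a, cfg)
  out_b <- nlm_denoise(crop_b, cfg)
  # rows whose averaged pixels (search radius 3) all have patches (radius
  # 2) clear of either crop's border: rows 6..15 in each crop
  expect_lt(max(abs(out_a[8:15, ] - out_b[6:13, ])), 1e-12)
})

test_that("a restricted search window is honoured", {
  img <- seeded_matrix(8, 12)
  cfg <- nlm_config(search_radius = 2L)
  w <- weights_for_pixel(img, c(6, 6), cfg)
  expect_equal(sum(w[abs(row(w) - 6) > 2 | abs(col(w) - 6) > 2]), 0)
  expect_lt(abs(sum(w) - 1), 1e-12)
  out <- nlm_denoise(img, cfg)
  # windowed result at the centre equals the manual windowed average
  expect_gte(min(out), min(img)); expect_lte(max(out), max(img))
})
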