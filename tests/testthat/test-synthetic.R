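test_that("generation is deterministic and leaves the RNG alone", {
  cfg <- sim_config(seed = 9, n_trials = 4)
  a <- simulate_erp(cfg)
  b <- simulate_erp(cfg)
  expect_identical(a, b)
  set.seed(55)
  before <- .Random.seed
  simulate_erp(cfg)
  expect_identical(.Random.seed, before)
})

test_that("noise-free configuration returns the clean trials", {
  cfg <- sim_config(seed = 1, n_trials = 3,
                    noise = list(pink_exponent = 1, alpha_freq_hz = 10,
                                 alpha_amp = 0, emg_band_hz = c(30, 120),
                                 emg_amp = 0),
                    target_snr_db = 300)
  sim <- simulate_erp(cfg)
  expect_lt(max(abs(sim$trials - sim$clean_per_trial)),
            1e-12 * max(abs(sim$clean_per_trial)))
})

test_that("the realised SNR matches the target within 0.1 dB", {
  sim <- simulate_erp(sim_config(seed = 3, n_trials = 10))
  expect_true(all(abs(sim$realized_snr_db - (-5)) < 0.1))
  # recompute from the returned matrices
  noise <- sim$trials - sim$clean_per_trial
  snr <- 10 * log10(rowSums(sim$clean_per_trial^2) / rowSums(noise^2))
  expect_true(all(abs(snr - (-5)) < 0.1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(fs = 250, duration_s = 1.001), "integer")
  expect_error(sim_config(components = list(
    list(polarity = 1, peak_time_s = .3, width_s = 0, amplitude_uv = 1))),
    "width")
})

test_that("the reference average behaves like an average", {
  a <- sinusoid(7, 100, 100)
  expect_equal(reference_from_trials(rbind(a, -a)), numeric(100))
  expect_equal(reference_from_trials(rbind(a)), a)
  sim <- simulate_erp(sim_config(seed = 1))
  ref <- reference_from_trials(sim$trials)
  expect_gt(cor(ref, sim$template), cor(sim$trials[1, ], sim$template))
})

test_that("averaging more trials tracks the template better on average", {
  gain <- function(seed, n) {
    sim <- simulate_erp(sim_config(seed = seed, n_trials = n))
    cor(reference_from_trials(sim$trials), sim$template)
  }
  r8 <- vapply(1:10, gain, numeric(1), n = 8L)
  r56 <- vapply(1:10, gain, numeric(1), n = 56L)
  expect_gt(mean(r56), mean(r8))
})

test_that("EMG-dominated noise has substantial power above 30 Hz", {
  cfg <- sim_config(seed = 2, n_trials = 5,
                    noise = list(pink_exponent = 1, alpha_freq_hz = 10,
                                 alpha_amp = 0.1, emg_band_hz = c(30, 120),
                                 emg_amp = 4))
  sim <- simulate_erp(cfg)
  noise <- sim$trials - sim$clean_per_trial
  frac_hf <- apply(noise, 1, function(x) {
    p <- Mod(fft(x))^2
    f <- (seq_along(x) - 1) * sim$fs / length(x)
    half <- f <= sim$fs / 2
    sum(p[half & f > 30]) / sum(p[half & f > 0])
  })
  expect_true(all(frac_hf > 0.25))
})

test_that("the 3-channel option applies gains 1.0/0.8/0.6", {
  sim <- simulate_erp(sim_config(seed = 4, n_trials = 6, n_channels = 3L))
  expect_length(sim$channels, 3L)
  expect_equal(dim(sim$channels[[2]]), dim(sim$trials))
  # with effectively no noise the channels are exact scaled copies
  clean <- simulate_erp(sim_config(seed = 4, n_trials = 2, n_channels = 3L,
                                   target_snr_db = 300))
  expect_lt(max(abs(clean$channels[[2]] - 0.8 * clean$channels[[1]])),
            1e-6 * max(abs(clean$channels[[1]])))
})
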