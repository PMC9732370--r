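test_that("CSV round trip is bit-exact and errors are informative", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- cbind(rep(0, 4), rep(1, 4))
  writeLines(rep("0,1", 4), path)
  rec <- load_csv(path, fs = 250)
  expect_equal(dim(rec$data), c(4L, 2L))
  expect_equal(unname(rec$data), m)

  set.seed(7)
  m2 <- matrix(rnorm(30), 10, 3)
  save_csv(m2, path)
  rec2 <- load_csv(path, fs = 250)
  expect_identical(unname(rec2$data), m2)

  writeLines(c("1,2", "3,oops"), path)
  expect_error(load_csv(path, fs = 250), "row 2")
  writeLines(c("1,2", "3"), path)
  expect_error(load_csv(path, fs = 250), "ragged")
  expect_error(load_csv(file.path(tempdir(), "nope.csv"), 250), "not found")
})

test_that("band-pass removes DC, keeps the passband, kills the stopband", {
  fs <- 250; n <- 1000
  dc <- rep(5, n)
  expect_lt(max(abs(bandpass(dc, fs)[101:900])), 1e-6 * 5)

  in_band <- sinusoid(10, fs, n)
  expect_lt(abs(central_amplitude(bandpass(in_band, fs)) - 1), 0.05)

  out_band <- sinusoid(60, fs, n)
  expect_lt(central_amplitude(bandpass(out_band, fs)), 0.05)

  expect_error(bandpass(in_band, fs, low = 0, high = 30), "band edges")
  expect_error(bandpass(in_band, fs, low = 2, high = 200), "band edges")
  expect_error(bandpass(rnorm(10), fs), "too short")
})

test_that("band-pass is close to idempotent in the passband", {
  fs <- 250
  x <- sinusoid(10, fs, 1000)
  once <- bandpass(x, fs)
  twice <- bandpass(once, fs)
  expect_lt(abs(central_amplitude(twice) / central_amplitude(once) - 1),
            0.01)
})

test_that("downsampling decimates with anti-aliasing", {
  y <- downsample(sinusoid(5, 1000, 1000), 1000, 250)
  expect_length(y, 250)
  ideal <- sinusoid(5, 250, 250)
  expect_gt(cor(y, ideal), 0.99)
  expect_error(downsample(rnorm(100), 1000, 300), "non-integer")
})

test_that("common average reference zeroes the channel mean", {
  rec <- recording(cbind(c(1, 2), c(3, 4)), fs = 100)
  out <- common_average_reference(rec)
  expect_equal(unname(out$data[1, ]), c(-1, 1))
  set.seed(3)
  rec2 <- recording(matrix(rnorm(500), 100, 5), fs = 100)
  out2 <- common_average_reference(rec2)
  expect_lt(max(abs(rowSums(out2$data))), 1e-12)
  # identical channels cancel entirely
  same <- recording(matrix(rep(rnorm(50), 3), 50, 3), fs = 100)
  expect_equal(max(abs(common_average_reference(same)$data)), 0)
  expect_error(common_average_reference(recording(matrix(1:5), fs = 10)),
               "single channel")
})

test_that("epoch extraction respects the half-open window", {
  fs <- 250
  n <- 600
  data <- matrix(seq_len(n), ncol = 1)
  rec <- recording(data, fs = fs, events = c(0L, 100L))
  ep <- extract_epochs(rec, 1L, duration_s = 1.0)
  expect_equal(dim(ep$trials), c(2L, 250L))
  # 0-based onset o maps to samples o+1 .. o+250 (sentinels outside)
  expect_equal(ep$trials[1, ], as.numeric(1:250))
  expect_equal(ep$trials[2, ], as.numeric(101:350))
  rec_bad <- recording(data, fs = fs, events = c(0L, n - 10L))
  expect_error(extract_epochs(rec_bad, 1L, 1.0), "event window")
})

test_that("56 events give 56 trials", {
  fs <- 250
  rec <- recording(matrix(rnorm(56 * 300), ncol = 1), fs = fs,
                   events = seq(0L, by = 250L, length.out = 56L))
  ep <- extract_epochs(rec, 1L, 1.0)
  expect_equal(nrow(ep$trials), 56L)
})
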