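test_that("zero-phase high-pass removes DC everywhere", {
  y <- highpassFilter(rep(5, 3000), fs = 30000)
  expect_lt(max(abs(y)), 5 * 1e-6)
  expect_length(y, 3000)
})

test_that("passband sine passes at the analytic squared-Butterworth gain", {
  fs <- 30000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 1000 * t)
  y <- highpassFilter(x, fs)
  central <- y[10000:20000]
  gain <- sqrt(butterHighpassGain2(1000, 250, 4))
  expect_lt(abs(max(abs(central)) - gain), 0.01)
  # zero phase lag: filtered output tracks the input at central samples
  expect_gt(stats::cor(central, x[10000:20000]), 0.999)
})

test_that("deep stopband sine is annihilated", {
  fs <- 30000
  t <- (0:(fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  y <- highpassFilter(x, fs)
  # analytic attenuation applied twice is ~6.5e-12; numerically the
  # reflection-padded edges dominate but stay far below 1e-6
  expect_lt(max(abs(y)), 1e-6)
})

test_that("filter is nearly idempotent on the passband", {
  fs <- 30000
  t <- (0:(fs / 2 - 1)) / fs
  x <- sin(2 * pi * 5000 * t)
  y1 <- highpassFilter(x, fs)
  y2 <- highpassFilter(y1, fs)
  a1 <- max(abs(y1[5000:10000]))
  a2 <- max(abs(y2[5000:10000]))
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("invalid cutoff and too-short traces are rejected", {
  cfg <- detectionConfig(filterCutoffHz = 16000)
  expect_error(highpassFilter(rnorm(100), 30000, cfg), "Nyquist")
  expect_error(highpassFilter(rnorm(10), 30000), "too short")
})
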