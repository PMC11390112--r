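test_that("cone and sphere volume formulas are exact", {
  expect_equal(estimateVolume(1, 3, "cone")$volume_mm3, pi)
  # the 1.5 mm-diameter cavitation as a sphere
  expect_equal(estimateVolume(0.75, geometry = "sphere")$volume_mm3,
               4 / 3 * pi * 0.75^3)
  expect_equal(round(estimateVolume(0.75, geometry = "sphere")$volume_mm3, 5),
               1.76715)
  # photo-sourced cone without height: height = radius
  v <- estimateVolume(0.5, geometry = "cone", source = "photo")
  expect_equal(v$height_mm, 0.5)
  expect_equal(round(v$volume_mm3, 5), 0.1309)
  expect_warning(estimateVolume(1, 2, "sphere"), "ignored")
  expect_error(estimateVolume(-1, 1, "cone"), "positive")
  expect_error(estimateVolume(0.5, geometry = "cone"), "height required")
})

test_that("volume is strictly increasing in radius and kill-radius inverts it", {
  r <- seq(0.1, 2, by = 0.1)
  v <- vapply(r, function(x) estimateVolume(x, geometry = "sphere")$volume_mm3,
              numeric(1))
  expect_true(all(diff(v) > 0))
  expect_equal(killRadius(v), r, tolerance = 1e-9)
  expect_equal(killRadius(0.268), 0.4, tolerance = 1e-3)
})

test_that("noiseless exponential data are fit exactly", {
  t <- 0:3
  m <- fitExponential(t, 2 * exp(0.5 * t))
  expect_equal(m$a, 2, tolerance = 1e-8)
  expect_equal(m$b, 0.5, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-8)
  expect_error(fitExponential(1:2, c(1, 2)), "insufficient")
})

test_that("exponential-rate recovery under multiplicative noise", {
  a <- 5.4e-7; b <- 5.6
  t <- seq(0.2, 1.4, length.out = 20)
  v <- withr::with_seed(1, a * exp(b * t) * (1 + 0.1 * rnorm(20)))
  m <- fitExponential(t, v)
  expect_lt(abs(m$b - b) / b, 0.05)
})

test_that("R-squared degrades monotonically-ish along a seeded noise ladder", {
  a <- 2; b <- 0.8
  t <- seq(0, 2, length.out = 25)
  r2 <- vapply(c(0, 0.05, 0.15, 0.4), function(s) {
    v <- withr::with_seed(11, a * exp(b * t) * exp(s * rnorm(25)))
    fitExponential(t, v)$r_squared
  }, numeric(1))
  expect_equal(r2[1], 1, tolerance = 1e-8)
  expect_true(all(diff(r2) < 0))
})

test_that("volume predictions are monotone in duration for b > 0", {
  m <- list(a = 5.4e-7, b = 5.6)
  expect_equal(predictVolume(m, 0), 5.4e-7)
  expect_equal(predictVolume(m, 1), 5.4e-7 * exp(5.6))
  t <- seq(-5, 2, by = 0.25)
  expect_true(all(diff(predictVolume(m, t)) > 0))
  expect_lt(predictVolume(m, -100), 1e-200 * 1e150) # -> 0+
})

test_that("device calculators follow Ohm's law and the supply rails", {
  expect_equal(maxLoadImpedance(450, -450, 150), 6)
  expect_equal(maxLoadImpedance(450, -450, 300), 3)
  expect_equal(maxLoadImpedance(12, -12, 150), 0.16)
  expect_error(maxLoadImpedance(450, -450, 0), "positive")
  expect_equal(parasiticResistance(12, 10), 1.2)
  expect_equal(parasiticResistance(12, 20), 0.6)
  expect_equal(parasiticResistance(12, 12), 1)
  expect_error(parasiticResistance(12, 0), "non-zero")
  expect_error(parasiticResistance(12, -5), "capacitive")
  expect_equal(maxOutputVoltage(450, -450), 900)
  expect_equal(arraySpan(4, 4), sqrt(32))
  expect_gte(arraySpan(4, 4), 5.6)
  expect_equal(arraySpan(3, 4), 5)
})

test_that("calculator outputs scale as their formulas dictate", {
  for (s in c(0.5, 2, 10)) {
    expect_equal(maxLoadImpedance(450 * s, -450 * s, 150),
                 s * maxLoadImpedance(450, -450, 150))
    expect_equal(maxLoadImpedance(450, -450, 150 * s),
                 maxLoadImpedance(450, -450, 150) / s)
    expect_equal(parasiticResistance(12 * s, 10),
                 s * parasiticResistance(12, 10))
    expect_equal(arraySpan(4 * s, 4 * s), s * arraySpan(4, 4))
    expect_equal(estimateVolume(0.7 * s, geometry = "sphere")$volume_mm3,
                 s^3 * estimateVolume(0.7, geometry = "sphere")$volume_mm3)
  }
})
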