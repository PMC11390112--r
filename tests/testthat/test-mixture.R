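test_that("BIC selects one component for a single Gaussian", {
  x <- withr::with_seed(42, rnorm(500, 0, 0.05))
  fit <- fitDeltaRMixture(x, seed = 1)
  expect_identical(fit@k, 1L)
  expect_equal(fit@means, mean(x), tolerance = 1e-9)
})

test_that("a well-separated mixture yields k = 2 with the 0-mean match", {
  x <- withr::with_seed(43, c(rnorm(250, 0, 0.05), rnorm(250, -1, 0.1)))
  fit <- fitDeltaRMixture(x, seed = 1)
  expect_identical(fit@k, 2L)
  mc <- matchComponent(fit)
  expect_lt(abs(mc["mean"]), 0.02)
  expect_lt(abs(min(fit@means) + 1), 0.05)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-12)
})

test_that("mixture parameters agree with an independent EM implementation", {
  suppressMessages(library(mclust))
  x <- withr::with_seed(44, c(rnorm(300, 0.02, 0.06), rnorm(150, -0.8, 0.15)))
  fit <- fitDeltaRMixture(x, seed = 2)
  ref <- mclust::Mclust(x, G = fit@k, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit@means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
  expect_equal(sort(fit@sds),
               sort(sqrt(as.numeric(ref$parameters$variance$sigmasq))),
               tolerance = 0.05)
})

test_that("too few observations are rejected", {
  expect_error(fitDeltaRMixture(rnorm(5)), "insufficient")
})

test_that("fits are invariant to observation order for fixed seeds", {
  x <- withr::with_seed(45, c(rnorm(100, 0, 0.05), rnorm(80, -0.7, 0.1)))
  f1 <- fitDeltaRMixture(x, seed = 9)
  f2 <- fitDeltaRMixture(withr::with_seed(1, sample(x)), seed = 9)
  expect_identical(f1@k, f2@k)
  expect_identical(f1@means, f2@means)
  expect_identical(f1@weights, f2@weights)
})

test_that("degenerate clusters hit the variance floor with a warning", {
  x <- c(rep(0.5, 30), withr::with_seed(46, rnorm(30, -1, 0.1)))
  expect_warning(fit <- fitDeltaRMixture(x, seed = 3), "floored")
  expect_true(all(fit@sds > 0))
})
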