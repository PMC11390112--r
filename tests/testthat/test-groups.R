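test_that("day-pair enumeration matches a brute-force application of the rules", {
  g <- buildDayPairs(1:13, lesionDay = 4)
  # brute force over all ordered pairs
  expected <- list()
  for (a in 1:13) for (b in 1:13) {
    if (b <= a || b - a > 4) next
    pa <- a - 4; pb <- b - 4
    grp <- if (pa <= 0 && pb <= 0) "pre_pre"
           else if (pa <= 0 && pb >= 1 && pb <= 3) "pre_post"
           else if (pa >= 4 && pa <= 7 && pb >= 4 && pb <= 7) "post_post"
           else NA
    if (!is.na(grp)) expected[[length(expected) + 1]] <-
      data.frame(day_a = a, day_b = b, group = grp)
  }
  expected <- do.call(rbind, expected)
  expect_identical(nrow(g), nrow(expected))
  expect_identical(g[, c("day_a", "day_b", "group")], expected)
  # stated memberships
  expect_true(any(g$day_a == 1 & g$day_b == 3 & g$group == "pre_pre"))
  expect_true(any(g$day_a == 4 & g$day_b == 6 & g$group == "pre_post"))
  expect_true(any(g$day_a == 9 & g$day_b == 11 & g$group == "post_post"))
  # exclusions: over-separated, acute-late spanning
  expect_false(any(g$day_a == 1 & g$day_b == 6))
  expect_false(any(g$day_a == 6 & g$day_b == 9))
})

test_that("separation switch and empty groups behave as documented", {
  g3 <- buildDayPairs(1:13, lesionDay = 4, maxSeparation = 3)
  expect_true(all(g3$separation <= 3))
  expect_warning(buildDayPairs(1:5, lesionDay = 4), "post_post")
})

test_that("median test reproduces hand-computed contingency results", {
  mt <- medianTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mt$statistic, 6)
  expect_equal(mt$p_value, pchisq(6, 1, lower.tail = FALSE))
  expect_true(mt$significant) # 0.0143 < 0.0167
  expect_equal(mt$alpha_corrected, 0.05 / 3)
  # identical groups: degenerate table
  mt0 <- medianTest(rep(50, 3), rep(50, 3))
  expect_equal(mt0$statistic, 0)
  expect_equal(mt0$p_value, 1)
  expect_false(mt0$significant)
})

test_that("median test is exchangeable within groups", {
  x <- withr::with_seed(1, runif(9, 40, 90))
  y <- withr::with_seed(2, runif(6, 30, 80))
  ref <- medianTest(x, y)
  for (i in 1:5) {
    perm <- medianTest(withr::with_seed(i, sample(x)),
                       withr::with_seed(i + 10, sample(y)))
    expect_identical(perm$statistic, ref$statistic)
    expect_identical(perm$p_value, ref$p_value)
  }
})

test_that("median test agrees with the brute-force oracle on random groups", {
  for (i in 1:200) {
    xy <- withr::with_seed(i, {
      nx <- sample(3:12, 1)
      ny <- sample(3:12, 1)
      list(x = round(runif(nx, 0, 100), 1), y = round(runif(ny, 0, 100), 1))
    })
    got <- medianTest(xy$x, xy$y)
    ref <- bruteMedianTest(xy$x, xy$y)
    expect_lt(abs(got$statistic - ref$statistic), 1e-9)
    expect_lt(abs(got$p_value - ref$p), 1e-9)
  }
})

test_that("null rejection rate at the corrected threshold is conservative", {
  rej <- vapply(1:2000, function(i) {
    xy <- withr::with_seed(100000 + i, {
      list(x = rnorm(6, 80, 8), y = rnorm(9, 80, 8))
    })
    medianTest(xy$x, xy$y)$significant
  }, logical(1))
  expect_lte(mean(rej), 0.025)
})
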