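test_that("waveform samples are standardised, trough-aligned, seeded", {
  geom <- smallGeom()
  pop <- clusterPop(geom)
  rec <- renderSession(pop, 1, durationS = 8, seed = 11)
  det <- detectSession(rec)
  sm <- det$snippets[[1]]
  ws <- sampleWaveforms(sm, n = 100, seed = 3, day = 1, minEvents = 30)
  expect_s4_class(ws, "WaveformSample")
  expect_identical(nrow(ws@mat), 100L)
  expect_lt(max(abs(rowMeans(ws@mat))), 1e-12)
  expect_lt(max(abs(apply(ws@mat, 1, sd) - 1)), 1e-12)
  expect_true(all(apply(ws@mat, 1, which.min) == 17L))
  # same seed -> same subset; different seed -> (almost surely) different
  ws2 <- sampleWaveforms(sm, n = 100, seed = 3, day = 1, minEvents = 30)
  expect_identical(ws@mat, ws2@mat)
  # fewer accepted than requested: all rows, flagged undersized
  wsAll <- sampleWaveforms(sm, n = 1e6, seed = 3, day = 1, minEvents = 30)
  expect_true(wsAll@undersized)
  expect_identical(nrow(wsAll@mat), nAccepted(sm))
})

test_that("electrodes below the comparability floor yield a marker", {
  sm <- new("SnippetMatrix", electrode = 5L,
            snippets = matrix(rnorm(10 * 48), 10),
            eventTimes = 1:10 * 100L, accepted = rep(TRUE, 10), fs = 30000)
  out <- sampleWaveforms(sm, seed = 1, day = 2, minEvents = 100)
  expect_true(isNonComparable(out))
  expect_identical(out$nAccepted, 10L)
})

test_that("self-projection is the identity and self delta-r is zero", {
  geom <- smallGeom()
  ws <- electrodeSample(clusterPop(geom), seedR = 11, seedS = 21)
  pr <- projectPair(ws, ws)
  expect_identical(pr$pointsA, pr$pointsB)
  expect_identical(deltaR(ws, ws), 0)
})

test_that("two repeated row-templates project to two plane locations", {
  a <- sin(2 * pi * (1:48) / 48)
  b <- cos(2 * pi * (1:48) / 24)
  std <- function(v) (v - mean(v)) / sd(v)
  m <- rbind(
    matrix(rep(std(a), 50), nrow = 50, byrow = TRUE),
    matrix(rep(std(b), 50), nrow = 50, byrow = TRUE)
  )
  ws <- new("WaveformSample", electrode = 1L, day = 1L, mat = m,
            undersized = FALSE, samplingSeed = 1L)
  pr <- projectPair(ws, ws)
  locs <- unique(round(pr$pointsA, 9))
  expect_identical(nrow(locs), 2L)
})

test_that("all-identical rows are a degenerate sample", {
  m <- matrix(rep((1:48 - mean(1:48)) / sd(1:48), 20), nrow = 20,
              byrow = TRUE)
  ws <- new("WaveformSample", electrode = 1L, day = 1L, mat = m,
            undersized = FALSE, samplingSeed = 1L)
  expect_error(projectPair(ws, ws), "degenerate")
})

test_that("median radius uses the lower-median convention", {
  expect_equal(medianRadius(cbind(c(3), c(4))), 5)
  theta <- seq(0, 2 * pi, length.out = 21)[-21]
  expect_equal(medianRadius(cbind(2 * cos(theta), 2 * sin(theta))), 2)
  # norms 1,2,3,4 -> lower median 2
  pts <- cbind(c(1, 2, 3, 4), 0)
  expect_equal(medianRadius(pts), 2)
  expect_error(medianRadius(matrix(numeric(), 0, 2)), "empty")
})

test_that("per-row standardisation removes pure gain changes", {
  geom <- smallGeom()
  pop <- clusterPop(geom)
  rec <- renderSession(pop, 1, durationS = 8, seed = 11)
  det <- detectSession(rec)
  sm <- det$snippets[[1]]
  smScaled <- sm
  smScaled@snippets <- sm@snippets * 3
  wsA <- sampleWaveforms(sm, seed = 3, day = 1, minEvents = 30)
  wsB <- sampleWaveforms(smScaled, seed = 3, day = 1, minEvents = 30)
  expect_equal(deltaR(wsA, wsB), 0, tolerance = 1e-12)
})

test_that("noise-dominated day-b samples drive delta-r negative", {
  geom <- smallGeom()
  wsA <- electrodeSample(clusterPop(geom), seedR = 11, seedS = 21)
  drs <- vapply(1:5, function(s) deltaR(wsA, noiseSample(seed = s)),
                numeric(1))
  expect_true(all(drs < 0))
})

test_that("categories partition the line around the match component", {
  fit <- new("MixtureFit", k = 2L, weights = c(0.8, 0.2),
             means = c(0.01, -1), sds = c(0.1, 0.2),
             bicByK = data.frame(k = 1:2, logLik = c(0, 0), bic = c(1, 0)),
             matchComponent = 1L, logLik = 0, n = 100L)
  mu <- 0.01; s <- 0.1
  expect_identical(as.character(categorizeDeltaR(mu, fit)), "match")
  expect_identical(as.character(categorizeDeltaR(mu + 1.5 * s, fit)),
                   "small_increase")
  expect_identical(as.character(categorizeDeltaR(mu - 3 * s, fit)),
                   "large_decrease")
  # boundaries: exactly one category each, no gaps anywhere on a grid
  z <- seq(-4, 4, by = 0.01)
  cats <- categorizeDeltaR(mu + z * s, fit)
  expect_false(anyNA(cats))
  # monotone non-decreasing category order along the line
  ord <- as.integer(cats)
  expect_true(all(diff(ord) >= 0))
})

test_that("percent match uses the fixed array denominator", {
  expect_equal(percentMatch(rep("match", 96)), 100)
  expect_equal(percentMatch(rep(c("match", "large_decrease"), each = 48)), 50)
  expect_equal(percentMatch(rep("small_increase", 96)), 0)
  expect_error(percentMatch("match", nElectrodes = 0), "positive")
})
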