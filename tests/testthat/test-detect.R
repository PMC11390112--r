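test_that("RMS threshold follows the stated definition", {
  expect_equal(rmsThreshold(rep(3, 30000), fs = 30000), -12)
  t <- seq(0, 1, by = 1 / 30000)
  expect_equal(rmsThreshold(sin(2 * pi * 100 * t), fs = 30000),
               -4 / sqrt(2), tolerance = 1e-3)
  expect_error(rmsThreshold(rep(0, 1000), fs = 30000), "degenerate")
})

test_that("RMS window uses the first minute, or the whole shorter trace", {
  x <- c(rep(1, 60 * 100), rep(10, 30 * 100)) # loud tail after 60 s at fs=100
  expect_equal(rmsThreshold(x, fs = 100), -4)
  expect_equal(rmsThreshold(x[1:3000], fs = 100), -4)
})

pulseTrace <- function(at, ampUv = 100, n = 3000) {
  x <- numeric(n)
  w <- spikeTemplate() * ampUv
  for (a in at) x[(a - 16):(a + 31)] <- x[(a - 16):(a + 31)] + w
  x
}

test_that("single pulse yields one event at its trough", {
  x <- pulseTrace(1000)
  ev <- detectEvents(x, -40)
  expect_identical(ev, 1000L)
  expect_identical(detectEvents(rep(0.1, 1000) * sin(1:1000), -40), integer())
})

test_that("dead time merges pulses closer than 1.6 ms and keeps distant ones", {
  # 5 ms apart (150 samples): two events; 0.5 ms (15 samples): one
  x2 <- pulseTrace(c(1000, 1150))
  x1 <- pulseTrace(c(1000, 1015))
  expect_length(detectEvents(x2, -40), 2L)
  expect_length(detectEvents(x1, -40), 1L)
  # agree with the naive reference scan on both
  expect_identical(detectEvents(x2, -40), naiveDetect(x2, -40))
  expect_identical(detectEvents(x1, -40), naiveDetect(x1, -40))
})

test_that("detection agrees exactly with the naive scan on random traces", {
  for (i in 1:200) {
    x <- withr::with_seed(i, {
      tr <- stats::rnorm(600)
      nPulse <- sample(0:3, 1)
      if (nPulse > 0) {
        at <- sample(40:560, nPulse)
        for (a in at) {
          tr[(a - 16):(a + 31)] <- tr[(a - 16):(a + 31)] + spikeTemplate() * 8
        }
      }
      tr
    })
    expect_identical(detectEvents(x, -3.5), naiveDetect(x, -3.5))
  }
})

test_that("snippet indexing brackets the trough as 16 + 32 samples", {
  x <- pulseTrace(1000)
  sm <- extractSnippets(x, 1000L, electrode = 7L)
  expect_identical(dim(sm@snippets), c(1L, 48L))
  expect_identical(as.numeric(sm@snippets[1, ]), x[984:1031])
  expect_identical(which.min(sm@snippets[1, ]), 17L)
  # snippet duration is 48 samples at 30 kHz = 1.6 ms
  expect_equal(48 / sm@fs, 1.6e-3)
})

test_that("events too close to the trace edge are dropped", {
  x <- c(spikeTemplate() * 100, numeric(500))
  sm <- extractSnippets(x, 10L)
  expect_identical(nrow(sm@snippets), 0L)
})

test_that("QC rejects over-amplitude and over-wide waveforms", {
  w <- spikeTemplate() # trough -1, derivative extrema ~12 samples apart
  # trough -250 uV, rebound +100 uV: peak-to-trough 350 uV
  tooBig <- ifelse(w < 0, w * 250, w * (100 / max(w)))
  ok <- w * 80 # p2p ~116 uV
  # slow half-sine valley: steepest fall at the first sample, steepest
  # rise at the last -> unique derivative extrema 46 samples apart (1.5 ms)
  tri <- -100 * sin(pi * (0:47) / 47)
  sm <- new("SnippetMatrix", electrode = 1L,
            snippets = rbind(tooBig, ok, tri),
            eventTimes = c(100L, 200L, 300L), accepted = rep(TRUE, 3),
            fs = 30000)
  out <- qcFilter(sm)
  expect_identical(out@accepted, c(FALSE, TRUE, FALSE))
})

test_that("tightening QC caps never increases the accepted count", {
  geom <- smallGeom()
  pop <- clusterPop(geom)
  rec <- renderSession(pop, 1, durationS = 3, seed = 3)
  det <- detectSession(rec)
  sm <- det$snippets[[1]]
  base <- nAccepted(qcFilter(sm))
  for (cap in c(250, 200, 150, 100)) {
    expect_lte(nAccepted(qcFilter(sm, detectionConfig(amplitudeCapUv = cap))),
               base)
  }
  for (wc in c(0.8, 0.6, 0.4, 0.2)) {
    expect_lte(nAccepted(qcFilter(sm, detectionConfig(widthCapMs = wc))),
               base)
  }
})

test_that("session summary divides by the effective duration", {
  mk <- function(times) {
    n <- length(times)
    snips <- if (n) matrix(rep(spikeTemplate(), each = n), nrow = n)
             else matrix(numeric(), 0, 48)
    new("SnippetMatrix", electrode = 1L, snippets = snips,
        eventTimes = as.integer(times), accepted = rep(TRUE, n),
        fs = 30000)
  }
  # first event at sample 1: effective duration = full 60 s
  s <- mk(seq(1, 30000 * 60, length.out = 300))
  out <- sessionSummary(list(s), durationS = 60)
  expect_equal(out$rate, 5)
  # silent electrode: zero rate, flagged mean
  out2 <- sessionSummary(list(s, mk(integer())), durationS = 60)
  expect_equal(out2$rate[2], 0)
  expect_false(out2$mean_defined[2])
  expect_true(all(is.na(out2[2, paste0("w", 1:48)])))
  # inactive lead-in is excluded: 150 events after a 30 s silent start
  s3 <- mk(seq(30000 * 30, 30000 * 60, length.out = 150))
  out3 <- sessionSummary(list(s3), durationS = 60)
  expect_equal(out3$rate, 150 / (60 - (30000 * 30 - 1) / 30000))
  out4 <- sessionSummary(list(s3), durationS = 60, firstEventPolicy = "full")
  expect_equal(out4$rate, 2.5)
})
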