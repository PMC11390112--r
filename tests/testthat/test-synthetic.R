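test_that("population generation is deterministic and validated", {
  geom <- utahGeometry()
  p1 <- generatePopulation(geom, nNeurons = 200, nDays = 3, seed = 1)
  p2 <- generatePopulation(geom, nNeurons = 200, nDays = 3, seed = 1)
  expect_identical(p1@neurons, p2@neurons)
  expect_identical(p1@dayEffects, p2@dayEffects)
  p3 <- generatePopulation(geom, nNeurons = 200, nDays = 3, seed = 2)
  expect_false(identical(p1@neurons, p3@neurons))
  expect_error(generatePopulation(geom, nNeurons = 0), "positive")
  # rates inside the stated band, amplitudes negative
  expect_true(all(p1@neurons$rate >= 0.5 & p1@neurons$rate <= 20))
  expect_true(all(p1@neurons$peak_amplitude < 0))
})

test_that("neurons sit inside the array footprint plus one pitch", {
  geom <- utahGeometry()
  pop <- generatePopulation(geom, nNeurons = 500, seed = 3)
  lim <- c(-geom@pitchUm, 9 * geom@pitchUm + geom@pitchUm)
  expect_true(all(pop@neurons$x >= lim[1] & pop@neurons$x <= lim[2]))
  expect_true(all(pop@neurons$y >= lim[1] & pop@neurons$y <= lim[2]))
})

test_that("rendering is bit-deterministic for a fixed seed", {
  geom <- smallGeom()
  pop <- generatePopulation(geom, nNeurons = 10, seed = 1)
  r1 <- renderSession(pop, 1, durationS = 0.5, seed = 9)
  r2 <- renderSession(pop, 1, durationS = 0.5, seed = 9)
  expect_identical(r1@samples, r2@samples)
  r3 <- renderSession(pop, 1, durationS = 0.5, seed = 10)
  expect_false(identical(r1@samples, r3@samples))
})

test_that("noise-free single neuron render reproduces amplitude and rate", {
  geom <- smallGeom()
  tip <- electrodePositions(geom, 1L)
  nb <- data.frame(x = tip[1, "x"], y = tip[1, "y"], z = tip[1, "z"],
                   peak_amplitude = -100, rate = 5)
  pop <- populationFromTable(nb, geom, seed = 1)
  out <- renderSession(pop, 1, durationS = 10, noiseSdUv = 0, seed = 4,
                       returnGroundTruth = TRUE)
  trace <- channelTrace(out$recording, 1L)
  # rendered trough equals the at-tip amplitude (to quantisation)
  expect_equal(min(trace), -100, tolerance = 0.25)
  # ground-truth count within 3 Poisson SDs of rate * duration
  expect_lt(abs(nrow(out$spikes) - 50), 3 * sqrt(50) + 1)
  # detection recovers the rate: every spike found, within Poisson error
  det <- detectSession(out$recording)
  rate <- det$summary$rate[1]
  expect_lt(abs(rate - 5), 3 * sqrt(5 * 10) / 10)
})

test_that("a neuron 300 um from every tip is invisible above threshold", {
  geom <- smallGeom(1, 2) # two electrodes 400 um apart
  tips <- electrodePositions(geom)
  # equidistant point 300 um from both tips
  mid <- colMeans(tips)
  dz <- sqrt(300^2 - (geom@pitchUm / 2)^2)
  nb <- data.frame(x = mid["x"], y = mid["y"], z = mid["z"] + dz,
                   peak_amplitude = -150 / exp(-60 / 28), # a loud neuron
                   rate = 30)
  pop <- populationFromTable(nb, geom, seed = 1)
  rec <- renderSession(pop, 1, durationS = 5, noiseSdUv = 0, seed = 2)
  # default-noise threshold surrogate: -4 x 10 uV RMS
  for (ch in activeChannels(geom)) {
    expect_true(all(channelTrace(rec, ch) > -40))
  }
})

test_that("detectability boundary: near neurons found, far neurons not", {
  geom <- smallGeom(1, 2)
  tip <- electrodePositions(geom, 1L)
  mkpop <- function(dist) {
    nb <- data.frame(
      x = tip[1, "x"], y = tip[1, "y"], z = tip[1, "z"] + dist,
      peak_amplitude = -3000, # at-source; decays with distance
      rate = 25
    )
    populationFromTable(nb, geom, seed = 1)
  }
  matchFrac <- function(dist, seed) {
    out <- renderSession(mkpop(dist), 1, durationS = 8, seed = seed,
                         returnGroundTruth = TRUE)
    det <- detectSession(out$recording)
    ev <- det$snippets[[1]]@eventTimes
    truth <- out$spikes$sample
    if (!length(truth)) return(NA_real_)
    hits <- vapply(truth, function(s) any(abs(ev - s) <= 30), logical(1))
    mean(hits)
  }
  # 50 um: amplitude ~502 uV at tip -> QC may reject, but detection sees it
  expect_gte(matchFrac(50, 3), 0.99)
  # 200 um: amplitude ~2.4 uV, buried in 10 uV noise
  far <- matchFrac(200, 4)
  out <- renderSession(mkpop(200), 1, durationS = 8, seed = 4,
                       returnGroundTruth = TRUE)
  det <- detectSession(out$recording)
  # false/chance events only; at most 1% of true spikes matched by luck
  expect_lte(far, 0.01)
})

test_that("lesions only remove neurons, with the stated kill geometry", {
  geom <- utahGeometry()
  pop <- generatePopulation(geom, nNeurons = 400, nDays = 2, seed = 5)
  les <- lesionSpec(45, 46, 150, 45, dayOfLesion = 1)
  # zero volume: nothing changes
  p0 <- applyLesion(pop, les, volumeModel = 0)
  expect_identical(p0@neurons$alive, pop@neurons$alive)
  # huge volume: everything dies
  pAll <- applyLesion(pop, les, volumeModel = 4 / 3 * pi * 8^3)
  expect_true(all(!pAll@neurons$alive))
  expect_lte(nNeurons(pAll), nNeurons(pop))
  # sphere of 0.268 mm^3 -> kill radius 0.4 mm: a neuron 350 um from the
  # midpoint dies, one at 450 um survives
  tips <- electrodePositions(geom, c(45L, 46L))
  center <- colMeans(tips)
  nb <- data.frame(
    x = center["x"] + c(350, 450), y = rep(center["y"], 2),
    z = rep(center["z"], 2),
    peak_amplitude = c(-500, -500), rate = c(5, 5)
  )
  popT <- populationFromTable(nb, geom, seed = 1)
  popL <- applyLesion(popT, les, volumeModel = 0.268)
  expect_identical(popL@neurons$alive, c(FALSE, TRUE))
  expect_error(applyLesion(popT, lesionSpec(1, 2, 150, 45), 0.1),
               "not active")
})

test_that("post-lesion sessions silence killed neurons, pre-lesion unchanged", {
  geom <- smallGeom(1, 2)
  pop <- clusterPop(geom, nDays = 4)
  les <- lesionSpec(1, 2, 150, 45, dayOfLesion = 2)
  popL <- applyLesion(pop, les, volumeModel = 4 / 3 * pi * 8^3)
  pre <- renderSession(popL, 2, durationS = 2, noiseSdUv = 0, seed = 3)
  post <- renderSession(popL, 3, durationS = 2, noiseSdUv = 0, seed = 3)
  expect_lt(min(channelTrace(pre, 1L)), -40)  # spikes present
  expect_identical(min(channelTrace(post, 1L)), 0) # only silence
})

test_that("overlong sessions are rejected as a capacity error", {
  geom <- smallGeom()
  pop <- generatePopulation(geom, nNeurons = 4, seed = 1)
  expect_error(renderSession(pop, 1, durationS = 1e8), "capacity")
})
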