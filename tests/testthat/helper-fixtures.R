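# Shared in-code fixtures: small geometries and controlled populations.

smallGeom <- function(rows = 2L, cols = 2L) {
  utahGeometry(rows, cols, activeChannels = seq_len(rows * cols))
}

# A population of `length(dists)` neurons strung out along +x from the
# tip of `electrode`, with effective trough amplitudes `troughsUv` as
# seen at that tip.
clusterPop <- function(geom, electrode = 1L, dists = c(60, 90, 120),
                       troughsUv = c(120, 150, 90), rates = c(15, 20, 10),
                       nDays = 1L, seed = 5L, pTurnover = 0,
                       ampJitter = 0) {
  tip <- electrodePositions(geom, electrode)
  nb <- data.frame(
    x = as.numeric(tip[1, "x"]) + dists,
    y = rep(as.numeric(tip[1, "y"]), length(dists)),
    z = rep(as.numeric(tip[1, "z"]), length(dists)),
    peak_amplitude = -troughsUv / exp(-dists / 28),
    rate = rates
  )
  populationFromTable(nb, geom, nDays = nDays, seed = seed,
                      pTurnover = pTurnover, ampJitter = ampJitter)
}

# Render + detect one electrode and return its accepted waveform sample
electrodeSample <- function(pop, electrode = 1L, dur = 8, seedR = 11L,
                            seedS = 21L, day = 1L, minEvents = 30L) {
  rec <- renderSession(pop, day, durationS = dur, seed = seedR)
  det <- detectSession(rec)
  idx <- match(electrode, activeChannels(pop@geometry))
  sampleWaveforms(det$snippets[[idx]], seed = seedS, day = day,
                  minEvents = minEvents)
}

# Standardised white-noise waveform rows (what a silenced electrode's
# residual threshold crossings look like)
noiseSample <- function(n = 300L, seed = 7L, electrode = 1L) {
  m <- withr::with_seed(seed, matrix(stats::rnorm(n * 48L), n))
  m <- (m - rowMeans(m)) / apply(m, 1, stats::sd)
  new("WaveformSample", electrode = as.integer(electrode), day = 2L,
      mat = m, undersized = FALSE, samplingSeed = as.integer(seed))
}
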