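#' @include AllClasses.R population.R template.R
NULL

# refractory thinning: keep the first spike, drop any spike closer than
# minIsi to the last kept one. Guarantees snippets never self-overlap.
thinRefractory <- function(times, minIsiS) {
  if (length(times) < 2L) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= minIsiS) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Render one session's raw multichannel recording
#'
#' Every alive neuron fires as a homogeneous Poisson process (thinned to
#' a 1.6 ms minimum inter-spike interval so snippets never overlap
#' themselves); each spike adds the neuron's trough-normalised template,
#' scaled by its at-source amplitude, the exponential distance decay to
#' each electrode tip, the day's drift multipliers and -- for sessions
#' after the lesion day -- the lesion's perturbed-survivor multipliers.
#' White Gaussian noise of `noiseSdUv` is added and the trace is
#' quantised to 16-bit integer codes at `gainUv` microvolts per code.
#'
#' With the default decay length constant of 28 um, a neuron's amplitude
#' at 140 um is ~0.7% of its at-source value, which confines resolvable
#' units to roughly 50-140 um from a tip against 10 uV noise.
#'
#' @param population A [NeuronPopulation-class] with day effects covering
#'   `dayIndex`.
#' @param dayIndex Which simulated day to render.
#' @param durationS Session duration, seconds.
#' @param noiseSdUv Additive white-noise SD, microvolts.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed; the rendering is bit-deterministic given it.
#' @param gainUv Microvolts per integer code (0.25: 300 uV = 1200
#'   codes).
#' @param lengthConstantUm Amplitude-decay length constant (must match
#'   the one used to generate the population; both default to 28).
#' @param minAmpUv Contributions below this amplitude at an electrode are
#'   skipped as unresolvable.
#' @param returnGroundTruth If TRUE, also return the ground-truth spike
#'   times used.
#' @return A [Recording-class]; or, with `returnGroundTruth = TRUE`, a
#'   list with elements `recording` and `spikes` (data.frame: neuron
#'   `id`, `electrode` home channel, `time` s, `sample` trough index).
#' @examples
#' geom <- utahGeometry(4, 4, activeChannels = 1:16)
#' pop <- generatePopulation(geom, nNeurons = 8, seed = 1)
#' rec <- renderSession(pop, dayIndex = 1, durationS = 0.5, seed = 2)
#' rec
#' @export
renderSession <- function(population, dayIndex, durationS, noiseSdUv = 10,
                          fs = 30000, seed = 1L, gainUv = 0.25,
                          lengthConstantUm = 28, minAmpUv = 1,
                          returnGroundTruth = FALSE) {
  abortIf(!(durationS > 0), "duration must be positive")
  abortIf(noiseSdUv < 0, "noise SD must be non-negative")
  nSamp <- round(durationS * fs)
  abortIf(nSamp > .Machine$integer.max,
          "duration * fs exceeds the sample-index capacity")
  nSamp <- as.integer(nSamp)
  dayIndex <- as.integer(dayIndex)

  geom <- population@geometry
  nb <- population@neurons
  eff <- population@dayEffects[population@dayEffects$day == dayIndex, ]
  abortIf(nrow(eff) == 0L,
          sprintf("population has no day effects for day %d", dayIndex))
  eff <- eff[match(nb$id, eff$id), ]

  postLesion <- !is.na(population@lesionDay) &&
    dayIndex > population@lesionDay
  alive <- if (postLesion) nb$alive else rep(TRUE, nrow(nb))
  rate <- eff$rate * (if (postLesion) nb$lesion_rate_mult else 1)
  rate[!alive] <- 0
  ampSrc <- abs(eff$peak_amplitude) *
    (if (postLesion) nb$lesion_amp_mult else 1)

  tips <- electrodePositions(geom)
  # neurons x channels amplitude matrix after distance decay
  dmat <- sqrt(
    outer(nb$x, tips[, 1], "-")^2 + outer(nb$y, tips[, 2], "-")^2 +
      outer(nb$z, tips[, 3], "-")^2
  )
  ampMat <- ampSrc * exp(-dmat / lengthConstantUm)

  pre <- 16L
  post <- 31L

  withSeed(seed, {
    # spike trains first (fixed neuron order), then channel noise, so the
    # stream layout is stable
    spikeIdx <- vector("list", nrow(nb))
    for (i in seq_len(nrow(nb))) {
      if (rate[i] <= 0) {
        spikeIdx[[i]] <- integer()
        next
      }
      n <- stats::rpois(1, rate[i] * durationS)
      tt <- thinRefractory(sort(stats::runif(n, 0, durationS)), 48 / fs)
      s <- as.integer(round(tt * fs))
      spikeIdx[[i]] <- s[s > pre & s <= nSamp - post]
    }
    templates <- lapply(seq_len(nrow(nb)), function(i) {
      spikeTemplate(
        eff$trough_sd_ms[i], eff$rebound_delay_ms[i], eff$rebound_frac[i],
        fs = fs
      )
    })

    samples <- t(.renderChannels(
      nChannels(geom), nSamp, noiseSdUv, gainUv, spikeIdx, templates,
      ampMat, minAmpUv, pre
    ))

    rec <- new("Recording",
      samples = samples, fs = fs, gainUv = gainUv, durationS = durationS,
      dayIndex = dayIndex, geometry = geom
    )
    if (!returnGroundTruth) return(rec)
    spikes <- data.frame(
      id = rep(nb$id, lengths(spikeIdx)),
      electrode = rep(nb$electrode, lengths(spikeIdx)),
      sample = unlist(spikeIdx) %||% integer()
    )
    spikes$time <- spikes$sample / fs
    list(recording = rec, spikes = spikes)
  })
}
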