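#' @include AllClasses.R geometry.R template.R
NULL

# shape-parameter draws shared by initial generation and day-to-day
# replacement of neurons
drawShapes <- function(n) {
  data.frame(
    trough_sd_ms = stats::runif(n, 0.08, 0.14),
    rebound_delay_ms = stats::runif(n, 0.30, 0.50),
    rebound_frac = stats::runif(n, 0.35, 0.55)
  )
}

drawRates <- function(n, rateRange) {
  exp(stats::runif(n, log(rateRange[1]), log(rateRange[2])))
}

#' Generate a ground-truth neuron population
#'
#' Simulates the local population an intracortical array records from.
#' Each neuron is assigned a home electrode and placed at a uniform
#' random distance inside the resolvable band around that electrode's
#' tip (50-140 um: the multi-unit "hash" zone). Firing rates are
#' log-uniform on `rateRange`. At-source spike amplitudes are chosen so
#' that the amplitude reaching the home electrode after exponential
#' distance decay (length constant `lengthConstantUm`) is uniform on
#' `troughRangeUv` -- i.e. the population is parameterised by what the
#' electrode sees, which is the quantity the recordings constrain.
#'
#' Day-to-day drift: on each day after the first, each electrode's
#' cluster is independently hit with probability `pTurnover`, replacing
#' one of its neurons (new waveform shape, rate and effective
#' amplitude; same location); surviving neurons' amplitudes are
#' jittered by up to +/- `ampJitter`. Parameterising turnover at the
#' electrode level keeps natural turnover over a few days minimal, the
#' regime the day-pair analysis assumes.
#'
#' @param geometry An [ArrayGeometry-class].
#' @param nNeurons Total number of neurons (> 0). Default twelve per
#'   active channel, emulating the multi-unit hash a chronic electrode
#'   records.
#' @param nDays Number of simulated days (drift effects are drawn for
#'   each).
#' @param seed Integer seed; the population is deterministic given it.
#' @param rateRange Firing-rate range, events/s (log-uniform draw).
#' @param troughRangeUv Range of trough amplitude reaching the home
#'   electrode, microvolts.
#' @param distRangeUm Distance band of neurons around their home tip.
#' @param lengthConstantUm Exponential amplitude-decay length constant.
#' @param pTurnover Per-day probability that an electrode's cluster
#'   has one neuron replaced.
#' @param ampJitter Half-width of the per-day multiplicative amplitude
#'   jitter.
#' @return A [NeuronPopulation-class].
#' @examples
#' pop <- generatePopulation(utahGeometry(), nNeurons = 20, seed = 1)
#' nNeurons(pop)
#' @export
generatePopulation <- function(geometry, nNeurons = 12L * nChannels(geometry),
                               nDays = 1L, seed = 1L,
                               rateRange = c(0.5, 20),
                               troughRangeUv = c(65, 185),
                               distRangeUm = c(50, 140),
                               lengthConstantUm = 28,
                               pTurnover = 0.05, ampJitter = 0.05) {
  abortIf(!(nNeurons > 0), "nNeurons must be positive")
  methods::validObject(geometry)
  nNeurons <- as.integer(nNeurons)
  chans <- activeChannels(geometry)
  tips <- electrodePositions(geometry)

  withSeed(seed, {
    # home electrodes: cycle through the array so coverage is even, in a
    # shuffled order so electrode id carries no information
    home <- sample(rep_len(chans, nNeurons))
    d <- stats::runif(nNeurons, distRangeUm[1], distRangeUm[2])
    # isotropic unit directions
    u <- matrix(stats::rnorm(3 * nNeurons), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    tipIdx <- match(home, chans)
    pos <- tips[tipIdx, , drop = FALSE] + u * d
    troughEff <- stats::runif(nNeurons, troughRangeUv[1], troughRangeUv[2])
    shapes <- drawShapes(nNeurons)
    neuronsTab <- data.frame(
      id = seq_len(nNeurons),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      electrode = home,
      peak_amplitude = -troughEff / exp(-d / lengthConstantUm),
      shapes,
      rate = drawRates(nNeurons, rateRange),
      alive = TRUE,
      lesion_amp_mult = 1, lesion_rate_mult = 1
    )

    # per-day drift: electrode-level replacement + amplitude jitter,
    # cumulative in day. Each day every electrode's cluster is hit with
    # probability pTurnover, replacing one of its neurons: turnover is
    # parameterised at the level the recordings observe, so a 4-day
    # separation stays in the minimal-natural-turnover regime the
    # day-pair design assumes.
    cur <- neuronsTab[, c(
      "peak_amplitude", "rate", "trough_sd_ms", "rebound_delay_ms",
      "rebound_frac"
    )]
    distDecay <- exp(-d / lengthConstantUm)
    effects <- vector("list", nDays)
    for (day in seq_len(nDays)) {
      replaced <- rep(FALSE, nNeurons)
      if (day > 1L) {
        hitChan <- chans[stats::runif(length(chans)) < pTurnover]
        for (ch in hitChan) {
          members <- which(neuronsTab$electrode == ch)
          if (length(members)) {
            replaced[members[sample.int(length(members), 1L)]] <- TRUE
          }
        }
        nr <- sum(replaced)
        if (nr > 0L) {
          cur$trough_sd_ms[replaced] <- stats::runif(nr, 0.08, 0.14)
          cur$rebound_delay_ms[replaced] <- stats::runif(nr, 0.30, 0.50)
          cur$rebound_frac[replaced] <- stats::runif(nr, 0.35, 0.55)
          cur$rate[replaced] <- drawRates(nr, rateRange)
          cur$peak_amplitude[replaced] <-
            -stats::runif(nr, troughRangeUv[1], troughRangeUv[2]) /
            distDecay[replaced]
        }
      }
      jit <- 1 + stats::runif(nNeurons, -ampJitter, ampJitter)
      effects[[day]] <- data.frame(
        day = day, id = neuronsTab$id, replaced = replaced,
        peak_amplitude = cur$peak_amplitude * jit,
        rate = cur$rate,
        trough_sd_ms = cur$trough_sd_ms,
        rebound_delay_ms = cur$rebound_delay_ms,
        rebound_frac = cur$rebound_frac
      )
    }

    new("NeuronPopulation",
      neurons = neuronsTab, dayEffects = do.call(rbind, effects),
      nDays = as.integer(nDays), geometry = geometry,
      lesionDay = NA_integer_
    )
  })
}

#' Build a population from an explicit neuron table
#'
#' Low-level constructor for controlled experiments: positions,
#' amplitudes, shapes and rates are supplied directly; per-day drift
#' effects are generated with the same replacement/jitter model as
#' [generatePopulation()] (set `pTurnover = 0, ampJitter = 0` for a
#' population that is identical every day).
#'
#' @param neurons data.frame with columns `x`, `y`, `z`,
#'   `peak_amplitude` (negative), `rate`, and optionally the shape
#'   columns `trough_sd_ms`, `rebound_delay_ms`, `rebound_frac`.
#' @inheritParams generatePopulation
#' @return A [NeuronPopulation-class].
#' @export
populationFromTable <- function(neurons, geometry, nDays = 1L, seed = 1L,
                                pTurnover = 0, ampJitter = 0,
                                rateRange = c(0.5, 20),
                                troughRangeUv = c(65, 185)) {
  n <- nrow(neurons)
  abortIf(n == 0L, "neurons table is empty")
  if (is.null(neurons$trough_sd_ms)) {
    neurons <- cbind(neurons, withSeed(seed, drawShapes(n)))
  }
  neurons$id <- seq_len(n)
  if (is.null(neurons$electrode)) {
    # nearest tip is the nominal home electrode
    tips <- electrodePositions(geometry)
    dmat <- outer(neurons$x, tips[, 1], "-")^2 +
      outer(neurons$y, tips[, 2], "-")^2 +
      outer(neurons$z, tips[, 3], "-")^2
    neurons$electrode <- activeChannels(geometry)[apply(dmat, 1, which.min)]
  }
  neurons$alive <- TRUE
  neurons$lesion_amp_mult <- 1
  neurons$lesion_rate_mult <- 1
  cols <- c(
    "id", "x", "y", "z", "electrode", "peak_amplitude", "trough_sd_ms",
    "rebound_delay_ms", "rebound_frac", "rate", "alive",
    "lesion_amp_mult", "lesion_rate_mult"
  )
  neurons <- neurons[, cols]

  effects <- withSeed(deriveSeed(seed, 7L), {
    cur <- neurons[, c(
      "peak_amplitude", "rate", "trough_sd_ms", "rebound_delay_ms",
      "rebound_frac"
    )]
    out <- vector("list", nDays)
    for (day in seq_len(nDays)) {
      replaced <- rep(FALSE, n)
      if (day > 1L && pTurnover > 0) {
        replaced <- stats::runif(n) < pTurnover
        nr <- sum(replaced)
        if (nr > 0L) {
          sh <- drawShapes(nr)
          cur$trough_sd_ms[replaced] <- sh$trough_sd_ms
          cur$rebound_delay_ms[replaced] <- sh$rebound_delay_ms
          cur$rebound_frac[replaced] <- sh$rebound_frac
          cur$rate[replaced] <- drawRates(nr, rateRange)
          # new neuron at the same spot: rescale the observed amplitude
          cur$peak_amplitude[replaced] <-
            cur$peak_amplitude[replaced] * stats::runif(nr, 0.7, 1.3)
        }
      }
      jit <- if (ampJitter > 0) 1 + stats::runif(n, -ampJitter, ampJitter)
             else rep(1, n)
      out[[day]] <- data.frame(
        day = day, id = neurons$id, replaced = replaced,
        peak_amplitude = cur$peak_amplitude * jit,
        rate = cur$rate,
        trough_sd_ms = cur$trough_sd_ms,
        rebound_delay_ms = cur$rebound_delay_ms,
        rebound_frac = cur$rebound_frac
      )
    }
    do.call(rbind, out)
  })

  new("NeuronPopulation",
    neurons = neurons, dayEffects = effects, nDays = as.integer(nDays),
    geometry = geometry, lesionDay = NA_integer_
  )
}

#' Spherical kill radius implied by a lesion volume
#'
#' Inverts the sphere volume formula: `r = (3V / 4 pi)^(1/3)`.
#'
#' @param volumeMm3 Lesion volume in cubic millimetres.
#' @return Radius in millimetres.
#' @examples
#' killRadius(0.268) # ~0.4 mm
#' @export
killRadius <- function(volumeMm3) {
  abortIf(any(volumeMm3 < 0), "volume must be non-negative")
  (3 * volumeMm3 / (4 * pi))^(1 / 3)
}

#' Apply an electrolytic lesion to a ground-truth population
#'
#' Converts the lesion's current and duration into a tissue volume via
#' `volumeModel`, inverts it to a spherical kill radius centred at the
#' midpoint of the anode and cathode tips, and terminates every neuron
#' inside that radius (`alive = FALSE`). Neurons in a configurable
#' annulus just outside the kill zone are modelled as perturbed
#' survivors: their spike amplitude and firing rate are scaled by
#' `annulusAmpMult` / `annulusRateMult`, emulating injury-related signal
#' degradation without death. Effects take hold for sessions rendered
#' after `lesion@dayOfLesion`; pre-lesion days are unaffected.
#'
#' @param population A [NeuronPopulation-class].
#' @param lesion A [LesionSpec-class].
#' @param volumeModel Either a function `(currentUa, durationS) ->`
#'   volume in cubic millimetres, or a single numeric volume (mm^3).
#' @param annulusUm Width of the perturbed-survivor annulus, micrometres.
#' @param annulusAmpMult,annulusRateMult Amplitude and rate multipliers
#'   for surviving neurons in the annulus.
#' @return The modified [NeuronPopulation-class] (neuron count never
#'   increases).
#' @examples
#' pop <- generatePopulation(utahGeometry(), nNeurons = 50, seed = 1)
#' les <- lesionSpec(45, 46, 150, 45, dayOfLesion = 4)
#' lesioned <- applyLesion(pop, les, volumeModel = 0.268)
#' sum(neurons(lesioned)$alive) <= nNeurons(pop)
#' @export
applyLesion <- function(population, lesion, volumeModel,
                        annulusUm = 250, annulusAmpMult = 0.5,
                        annulusRateMult = 0.5) {
  methods::validObject(lesion)
  geom <- population@geometry
  ok <- c(lesion@anode, lesion@cathode) %in% activeChannels(geom)
  abortIf(!all(ok), "lesion electrodes are not active channels of the geometry")

  vol <- if (is.function(volumeModel)) {
    volumeModel(lesion@currentUa, lesion@durationS)
  } else {
    as.numeric(volumeModel)
  }
  abortIf(!is.finite(vol) || vol < 0, "volume model returned an invalid volume")
  rUm <- killRadius(vol) * 1000

  tips <- electrodePositions(geom, c(lesion@anode, lesion@cathode))
  center <- colMeans(tips)
  nb <- population@neurons
  dist <- sqrt((nb$x - center["x"])^2 + (nb$y - center["y"])^2 +
               (nb$z - center["z"])^2)
  nb$alive <- nb$alive & (dist > rUm)
  inAnnulus <- dist > rUm & dist <= rUm + annulusUm
  nb$lesion_amp_mult[inAnnulus] <- nb$lesion_amp_mult[inAnnulus] * annulusAmpMult
  nb$lesion_rate_mult[inAnnulus] <- nb$lesion_rate_mult[inAnnulus] * annulusRateMult

  population@neurons <- nb
  population@lesionDay <- lesion@dayOfLesion
  population
}
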