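#' @include utils.R
NULL

# ---- ArrayGeometry ---------------------------------------------------------

#' Multielectrode array geometry
#'
#' Describes a rectangular intracortical microelectrode array: grid size,
#' inter-electrode pitch, shank length, and which grid sites are wired
#' ("active"). The default constructor [utahGeometry()] describes a
#' 10 x 10 Utah array with 400 um pitch, 1 mm shanks and 96 wired
#' channels (the four corner sites are unwired).
#'
#' @slot nRows,nCols Integer grid dimensions.
#' @slot pitchUm Inter-electrode spacing in micrometres.
#' @slot shankUm Electrode shank length in micrometres; tips sit at this
#'   depth below the array plane.
#' @slot activeChannels Integer ids (1-based, row-major grid order) of the
#'   wired electrodes.
#'
#' @seealso [utahGeometry()], [electrodePositions()]
#' @exportClass ArrayGeometry
setClass("ArrayGeometry",
  representation(
    nRows = "integer",
    nCols = "integer",
    pitchUm = "numeric",
    shankUm = "numeric",
    activeChannels = "integer"
  )
)

setValidity("ArrayGeometry", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid dimensions must be positive")
  if (!(object@pitchUm > 0)) msg <- c(msg, "pitch must be > 0")
  if (!(object@shankUm > 0)) msg <- c(msg, "shank length must be > 0")
  if (anyDuplicated(object@activeChannels))
    msg <- c(msg, "active channel ids must be unique")
  if (length(object@activeChannels) > object@nRows * object@nCols)
    msg <- c(msg, "more active channels than grid sites")
  if (length(object@activeChannels) &&
      (min(object@activeChannels) < 1L ||
       max(object@activeChannels) > object@nRows * object@nCols))
    msg <- c(msg, "active channel ids outside the grid")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ArrayGeometry", function(object) {
  cat(sprintf(
    "ArrayGeometry: %d x %d grid, %g um pitch, %g um shanks, %d active channels\n",
    object@nRows, object@nCols, object@pitchUm, object@shankUm,
    length(object@activeChannels)
  ))
})

#' @describeIn ArrayGeometry-class Number of active (wired) channels.
#' @param object,x An `ArrayGeometry`.
#' @export
nChannels <- function(x) length(x@activeChannels)

#' @describeIn ArrayGeometry-class Integer ids of the active channels.
#' @export
activeChannels <- function(x) x@activeChannels

# ---- DetectionConfig -------------------------------------------------------

#' Spike detection and quality-control parameters
#'
#' Bundles the filtering, thresholding, snippet-extraction and waveform
#' quality-control settings for the detection chain. Defaults follow the
#' standard chronic-array processing convention: fourth-order zero-phase
#' Butterworth high-pass at 250 Hz, threshold at -4x the RMS voltage of
#' the first minute, 48-sample snippets (16 points before the trough, the
#' trough, and 31 after), a 300 uV peak-to-trough amplitude cap and a
#' 1 ms width cap.
#'
#' @slot filterOrder,filterCutoffHz High-pass Butterworth order and
#'   cutoff (Hz).
#' @slot thresholdMultiplier Negative multiplier applied to the RMS
#'   voltage (default -4).
#' @slot rmsWindowS Length of the RMS estimation window in seconds
#'   (default 60; the full trace is used when shorter).
#' @slot preSamples,postSamples Samples kept before/after the trough
#'   (16 and 32; the trough is counted within the 32, giving 48 total).
#' @slot deadTimeSamples Threshold crossings within this many samples
#'   after an accepted event are ignored (default 48).
#' @slot amplitudeCapUv Peak-to-trough amplitude above which a snippet is
#'   rejected (default 300 uV).
#' @slot widthCapMs Derivative-peak separation above which a snippet is
#'   rejected (default 1 ms).
#'
#' @seealso [detectionConfig()]
#' @exportClass DetectionConfig
setClass("DetectionConfig",
  representation(
    filterOrder = "integer",
    filterCutoffHz = "numeric",
    thresholdMultiplier = "numeric",
    rmsWindowS = "numeric",
    preSamples = "integer",
    postSamples = "integer",
    deadTimeSamples = "integer",
    amplitudeCapUv = "numeric",
    widthCapMs = "numeric"
  )
)

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (object@filterOrder < 1L) msg <- c(msg, "filter order must be >= 1")
  if (!(object@filterCutoffHz > 0)) msg <- c(msg, "cutoff must be > 0")
  if (!(object@thresholdMultiplier < 0))
    msg <- c(msg, "threshold multiplier must be negative")
  if (object@preSamples + object@postSamples != 48L)
    msg <- c(msg, "preSamples + postSamples must equal 48")
  if (!(object@amplitudeCapUv > 0) || !(object@widthCapMs > 0))
    msg <- c(msg, "QC caps must be positive")
  if (object@deadTimeSamples < 0L) msg <- c(msg, "dead time must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DetectionConfig", function(object) {
  cat(sprintf(
    paste0(
      "DetectionConfig: HP Butterworth order %d @ %g Hz (zero-phase), ",
      "threshold %gx RMS(%gs),\n  snippet %d+%d samples, dead time %d, ",
      "caps: %g uV p2p, %g ms width\n"
    ),
    object@filterOrder, object@filterCutoffHz, object@thresholdMultiplier,
    object@rmsWindowS, object@preSamples, object@postSamples,
    object@deadTimeSamples, object@amplitudeCapUv, object@widthCapMs
  ))
})

# ---- NeuronPopulation ------------------------------------------------------

#' Ground-truth neuron population for the synthetic recording generator
#'
#' Holds one simulated local population: per-neuron positions (um, array
#' frame: x/y in the array plane, z depth), at-source spike amplitude,
#' biphasic waveform shape parameters, Poisson rate, alive flag and
#' lesion perturbation multipliers, together with per-day drift effects.
#'
#' @slot neurons data.frame with one row per neuron (columns `id`, `x`,
#'   `y`, `z`, `electrode`, `peak_amplitude`, `trough_sd_ms`,
#'   `rebound_delay_ms`, `rebound_frac`, `rate`, `alive`,
#'   `lesion_amp_mult`, `lesion_rate_mult`).
#' @slot dayEffects data.frame with one row per neuron per day giving the
#'   day's amplitude/rate multipliers and (possibly replaced) waveform
#'   shape parameters.
#' @slot nDays Number of simulated days.
#' @slot geometry The [ArrayGeometry-class] the population was generated
#'   for.
#' @slot lesionDay Day index after which lesion effects apply
#'   (`NA_integer_` when no lesion has been applied).
#'
#' @seealso [generatePopulation()], [applyLesion()], [renderSession()]
#' @exportClass NeuronPopulation
setClass("NeuronPopulation",
  representation(
    neurons = "data.frame",
    dayEffects = "data.frame",
    nDays = "integer",
    geometry = "ArrayGeometry",
    lesionDay = "integer"
  )
)

setValidity("NeuronPopulation", function(object) {
  msg <- character()
  need <- c(
    "id", "x", "y", "z", "electrode", "peak_amplitude", "trough_sd_ms",
    "rebound_delay_ms", "rebound_frac", "rate", "alive",
    "lesion_amp_mult", "lesion_rate_mult"
  )
  if (!all(need %in% names(object@neurons)))
    msg <- c(msg, "neurons table is missing required columns")
  else {
    if (any(object@neurons$rate < 0)) msg <- c(msg, "rates must be >= 0")
    if (any(object@neurons$peak_amplitude >= 0))
      msg <- c(msg, "peak amplitudes must be negative (trough-negative spikes)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "NeuronPopulation", function(object) {
  cat(sprintf(
    "NeuronPopulation: %d neurons (%d alive), %d day(s)%s\n",
    nrow(object@neurons), sum(object@neurons$alive), object@nDays,
    if (is.na(object@lesionDay)) ""
    else sprintf(", lesion after day %d", object@lesionDay)
  ))
})

#' @describeIn NeuronPopulation-class The per-neuron ground-truth table.
#' @param x A `NeuronPopulation`.
#' @export
neurons <- function(x) x@neurons

#' @describeIn NeuronPopulation-class Number of neurons.
#' @export
nNeurons <- function(x) nrow(x@neurons)

# ---- LesionSpec ------------------------------------------------------------

#' Electrolytic lesion parameters
#'
#' The anode/cathode electrode pair, direct-current amplitude, duration,
#' and the session index after which the lesion takes place. The in vivo
#' convention is 150 uA through two adjacent electrodes for 30 or 45 s.
#'
#' @slot anode,cathode Electrode ids (must differ).
#' @slot currentUa Current amplitude in microamps (> 0).
#' @slot durationS Duration of current delivery in seconds (> 0).
#' @slot dayOfLesion Session index after which the lesion occurs.
#'
#' @seealso [lesionSpec()], [applyLesion()]
#' @exportClass LesionSpec
setClass("LesionSpec",
  representation(
    anode = "integer",
    cathode = "integer",
    currentUa = "numeric",
    durationS = "numeric",
    dayOfLesion = "integer"
  )
)

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (object@anode == object@cathode) msg <- c(msg, "anode must differ from cathode")
  if (!(object@currentUa > 0)) msg <- c(msg, "current must be > 0")
  if (!(object@durationS > 0)) msg <- c(msg, "duration must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LesionSpec", function(object) {
  cat(sprintf(
    "LesionSpec: %g uA for %g s through electrodes %d (anode) / %d (cathode), after day %d\n",
    object@currentUa, object@durationS, object@anode, object@cathode,
    object@dayOfLesion
  ))
})

#' Construct a LesionSpec
#'
#' @param anode,cathode Electrode ids of the lesion pair.
#' @param currentUa Direct current amplitude, microamps.
#' @param durationS Duration of current delivery, seconds.
#' @param dayOfLesion Session index after which the lesion occurs.
#' @return A [LesionSpec-class] object.
#' @examples
#' lesionSpec(45, 46, currentUa = 150, durationS = 45, dayOfLesion = 4)
#' @export
lesionSpec <- function(anode, cathode, currentUa = 150, durationS = 45,
                       dayOfLesion = 1L) {
  new("LesionSpec",
    anode = as.integer(anode), cathode = as.integer(cathode),
    currentUa = currentUa, durationS = durationS,
    dayOfLesion = as.integer(dayOfLesion)
  )
}

# ---- Recording -------------------------------------------------------------

#' One session's multichannel voltage recording
#'
#' Raw (unfiltered) extracellular voltage as integer codes, one row per
#' active channel, plus sampling metadata and array geometry. Voltage in
#' microvolts is `samples * gainUv`.
#'
#' @slot samples Integer matrix, channels x time.
#' @slot fs Sampling rate, Hz (30000 for the emulated acquisition).
#' @slot gainUv Microvolts per integer code.
#' @slot durationS Session duration in seconds.
#' @slot dayIndex Session day index.
#' @slot geometry The [ArrayGeometry-class].
#'
#' @seealso [renderSession()], [readRecording()], [writeRecording()]
#' @exportClass Recording
setClass("Recording",
  representation(
    samples = "matrix",
    fs = "numeric",
    gainUv = "numeric",
    durationS = "numeric",
    dayIndex = "integer",
    geometry = "ArrayGeometry"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (!(object@fs > 0)) msg <- c(msg, "fs must be > 0")
  if (!(object@gainUv > 0)) msg <- c(msg, "gain must be > 0")
  if (anyNA(object@samples)) msg <- c(msg, "samples must be finite")
  if (nrow(object@samples) != nChannels(object@geometry))
    msg <- c(msg, "channel count must equal the number of active channels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: day %d, %d channels x %d samples (%.3g s @ %g Hz), gain %g uV/code\n",
    object@dayIndex, nrow(object@samples), ncol(object@samples),
    object@durationS, object@fs, object@gainUv
  ))
})

#' @describeIn Recording-class One channel's trace in microvolts.
#' @param x A `Recording`.
#' @param channel Active-channel id.
#' @export
channelTrace <- function(x, channel) {
  i <- match(channel, activeChannels(x@geometry))
  abortIf(is.na(i), sprintf("channel %s is not an active channel", channel))
  as.numeric(x@samples[i, ]) * x@gainUv
}

# ---- SnippetMatrix ---------------------------------------------------------

#' Per-electrode spike snippets
#'
#' The 48-sample, trough-aligned action-potential snippets detected on
#' one electrode, in microvolts, with event sample indices and the
#' quality-control acceptance mask.
#'
#' @slot electrode Electrode id.
#' @slot snippets Numeric matrix, events x 48, microvolts.
#' @slot eventTimes Integer sample index of each trough.
#' @slot accepted Logical QC mask, one flag per event.
#' @slot fs Sampling rate (Hz).
#'
#' @seealso [extractSnippets()], [qcFilter()], [sampleWaveforms()]
#' @exportClass SnippetMatrix
setClass("SnippetMatrix",
  representation(
    electrode = "integer",
    snippets = "matrix",
    eventTimes = "integer",
    accepted = "logical",
    fs = "numeric"
  )
)

setValidity("SnippetMatrix", function(object) {
  msg <- character()
  if (nrow(object@snippets) != length(object@eventTimes))
    msg <- c(msg, "row count must equal event count")
  if (length(object@accepted) != length(object@eventTimes))
    msg <- c(msg, "accepted mask must have one flag per event")
  if (ncol(object@snippets) != 48L && nrow(object@snippets) > 0L)
    msg <- c(msg, "snippets must have 48 columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SnippetMatrix", function(object) {
  cat(sprintf(
    "SnippetMatrix: electrode %d, %d events (%d accepted)\n",
    object@electrode, length(object@eventTimes), sum(object@accepted)
  ))
})

#' @describeIn SnippetMatrix-class Number of QC-accepted events.
#' @param x A `SnippetMatrix`.
#' @export
nAccepted <- function(x) sum(x@accepted)

#' @describeIn SnippetMatrix-class Matrix of accepted snippets only.
#' @export
acceptedSnippets <- function(x) x@snippets[x@accepted, , drop = FALSE]

# ---- WaveformSample --------------------------------------------------------

#' Standardised waveform sample for one electrode and day
#'
#' Up to 1000 accepted snippets, re-aligned so each row's trough sits at
#' column 17 (the 16 + 32 convention) and standardised per row to mean 0
#' and SD 1 across the 48 points.
#'
#' @slot electrode Electrode id.
#' @slot day Day index.
#' @slot mat Standardised waveform matrix, n x 48.
#' @slot undersized TRUE when fewer accepted snippets than requested were
#'   available.
#' @slot samplingSeed Seed used for the subsampling draw.
#'
#' @seealso [sampleWaveforms()], [projectPair()]
#' @exportClass WaveformSample
setClass("WaveformSample",
  representation(
    electrode = "integer",
    day = "integer",
    mat = "matrix",
    undersized = "logical",
    samplingSeed = "integer"
  )
)

setMethod("show", "WaveformSample", function(object) {
  cat(sprintf(
    "WaveformSample: electrode %d, day %d, %d x %d%s\n",
    object@electrode, object@day, nrow(object@mat), ncol(object@mat),
    if (object@undersized) " (undersized)" else ""
  ))
})

#' Marker for electrodes that cannot be compared across a day pair
#'
#' Returned by [sampleWaveforms()] when an electrode has fewer accepted
#' snippets than `minEvents`.
#'
#' @param electrode Electrode id.
#' @param day Day index.
#' @param nAccepted Number of accepted snippets found.
#' @return An object of S3 class `nonComparable`.
#' @export
nonComparable <- function(electrode = NA_integer_, day = NA_integer_,
                          nAccepted = 0L) {
  structure(
    list(electrode = electrode, day = day, nAccepted = nAccepted),
    class = "nonComparable"
  )
}

#' @rdname nonComparable
#' @param x Object to test.
#' @export
isNonComparable <- function(x) inherits(x, "nonComparable")

# ---- MixtureFit ------------------------------------------------------------

#' One-dimensional Gaussian mixture fit with BIC model selection
#'
#' EM fits for k = 1..kMax components; the reported model minimises the
#' Bayesian information criterion (ties broken toward smaller k). The
#' `matchComponent` is the component whose mean lies nearest zero: for
#' delta-r pools it represents electrode-days whose recorded multi-unit
#' composition did not change.
#'
#' @slot k Selected number of components.
#' @slot weights,means,sds Component parameters (weights sum to 1).
#' @slot bicByK data.frame of k, log-likelihood and BIC for each fitted k.
#' @slot matchComponent Index of the component with mean nearest 0.
#' @slot logLik Log-likelihood of the selected model.
#' @slot n Number of observations.
#'
#' @seealso [fitDeltaRMixture()], [categorizeDeltaR()]
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(
    k = "integer",
    weights = "numeric",
    means = "numeric",
    sds = "numeric",
    bicByK = "data.frame",
    matchComponent = "integer",
    logLik = "numeric",
    n = "integer"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  if (any(object@sds <= 0)) msg <- c(msg, "component SDs must be positive")
  if (object@matchComponent < 1L || object@matchComponent > object@k)
    msg <- c(msg, "matchComponent out of range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit: k = %d (BIC-selected over %d candidates), n = %d\n",
    object@k, nrow(object@bicByK), object@n
  ))
  for (j in seq_len(object@k)) {
    cat(sprintf(
      "  comp %d: weight %.3f, mean %+.4f, sd %.4f%s\n",
      j, object@weights[j], object@means[j], object@sds[j],
      if (j == object@matchComponent) "  [match]" else ""
    ))
  }
})

#' @describeIn MixtureFit-class Mean and SD of the match component.
#' @param x A `MixtureFit`.
#' @export
matchComponent <- function(x) {
  c(mean = x@means[x@matchComponent], sd = x@sds[x@matchComponent])
}
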