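#' @include AllClasses.R
NULL

#' Construct a DetectionConfig
#'
#' @param filterOrder Butterworth order (default 4).
#' @param filterCutoffHz High-pass cutoff (default 250 Hz).
#' @param thresholdMultiplier RMS multiplier for the detection threshold
#'   (default -4).
#' @param rmsWindowS RMS window length, seconds (default 60).
#' @param preSamples,postSamples Snippet window: `preSamples` points
#'   before the trough and `postSamples` from the trough on (16 + 32 =
#'   48 points, 1.6 ms at 30 kHz).
#' @param deadTimeSamples Crossings within this many samples of an
#'   accepted event are ignored (default 48).
#' @param amplitudeCapUv Peak-to-trough rejection cap (default 300 uV).
#' @param widthCapMs Waveform-width rejection cap (default 1 ms).
#' @return A [DetectionConfig-class].
#' @examples
#' detectionConfig()
#' @export
detectionConfig <- function(filterOrder = 4L, filterCutoffHz = 250,
                            thresholdMultiplier = -4, rmsWindowS = 60,
                            preSamples = 16L, postSamples = 32L,
                            deadTimeSamples = 48L, amplitudeCapUv = 300,
                            widthCapMs = 1.0) {
  new("DetectionConfig",
    filterOrder = as.integer(filterOrder), filterCutoffHz = filterCutoffHz,
    thresholdMultiplier = thresholdMultiplier, rmsWindowS = rmsWindowS,
    preSamples = as.integer(preSamples), postSamples = as.integer(postSamples),
    deadTimeSamples = as.integer(deadTimeSamples),
    amplitudeCapUv = amplitudeCapUv, widthCapMs = widthCapMs
  )
}

#' Zero-phase Butterworth high-pass filter
#'
#' Applies an order-`filterOrder` Butterworth high-pass forward and
#' backward (zero phase lag; the effective magnitude response is the
#' squared single-pass response). To suppress the start-up transients of
#' causal IIR filtering, the trace is extended at both ends by odd
#' reflection (up to 1000 samples) before the two passes, and the
#' extensions are discarded afterwards; a constant (DC) input therefore
#' maps to ~0 everywhere, not just away from the edges.
#'
#' @param trace Single-channel voltage series (numeric).
#' @param fs Sampling rate, Hz.
#' @param config A [DetectionConfig-class] supplying order and cutoff.
#' @return Filtered series, same length as the input.
#' @examples
#' t <- (0:2999) / 30000
#' x <- sin(2 * pi * 1000 * t) + 5 # 1 kHz riding on DC
#' y <- highpassFilter(x, 30000)
#' max(abs(y)) # ~1: DC removed, 1 kHz passed
#' @export
highpassFilter <- function(trace, fs, config = detectionConfig()) {
  abortIf(!(config@filterCutoffHz < fs / 2),
          "cutoff must be below the Nyquist frequency")
  n <- length(trace)
  abortIf(n <= 3L * config@filterOrder,
          "trace too short for the requested filter order")
  bf <- signal::butter(config@filterOrder, config@filterCutoffHz / (fs / 2),
                       type = "high")
  pad <- min(1000L, n - 1L)
  pre <- 2 * trace[1] - trace[(pad + 1):2]
  post <- 2 * trace[n] - trace[(n - 1):(n - pad)]
  xe <- c(pre, trace, post)
  y <- iirFilter(bf$b, bf$a, xe)
  y <- rev(iirFilter(bf$b, bf$a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# direct-form IIR y = filter(b, a, x); a[1] == 1 as returned by
# signal::butter. Compiled single pass.
iirFilter <- function(b, a, x) .iirPass(b, a, x)
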