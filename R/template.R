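#' @include AllClasses.R
NULL

#' Biphasic extracellular spike template
#'
#' A difference of two Gaussians in time: a sharp negative depolarisation
#' trough followed by a slower positive rebound. The template is
#' trough-normalised (minimum exactly -1, at sample `troughIndex`), so a
#' neuron's waveform is `peakAmplitude * spikeTemplate(...)` with
#' `peakAmplitude < 0 ... > 0` conventions handled by the caller
#' (amplitudes are stored negative; the template is multiplied by their
#' absolute value). Two Gaussian phases give the temporal derivative two
#' prominent peaks, which is what the waveform-width QC rule measures.
#'
#' @param troughSdMs SD of the trough Gaussian, milliseconds.
#' @param reboundDelayMs Delay of the rebound peak after the trough,
#'   milliseconds.
#' @param reboundFrac Rebound amplitude as a fraction of the trough
#'   depth.
#' @param fs Sampling rate, Hz.
#' @param nSamples Template length in samples (48 at 30 kHz = 1.6 ms).
#' @param troughIndex 1-based sample index of the trough (17: 16 points
#'   precede it).
#' @return Numeric vector of length `nSamples` with minimum -1 at
#'   `troughIndex`.
#' @examples
#' w <- spikeTemplate()
#' which.min(w) # 17
#' min(w)       # -1
#' @export
spikeTemplate <- function(troughSdMs = 0.11, reboundDelayMs = 0.4,
                          reboundFrac = 0.45, fs = 30000,
                          nSamples = 48L, troughIndex = 17L) {
  abortIf(!(troughSdMs > 0) || !(reboundDelayMs > 0),
          "template time constants must be positive")
  tMs <- (seq_len(nSamples) - troughIndex) * 1000 / fs
  reboundSd <- 1.8 * troughSdMs
  w <- -exp(-tMs^2 / (2 * troughSdMs^2)) +
    reboundFrac * exp(-(tMs - reboundDelayMs)^2 / (2 * reboundSd^2))
  # trough-normalise; the rebound tail never outweighs the trough for
  # the supported parameter ranges, so the minimum stays at troughIndex
  w <- w / abs(min(w))
  shift <- troughIndex - which.min(w)
  if (shift != 0) {
    w <- if (shift > 0) c(rep(w[1], shift), w[seq_len(nSamples - shift)])
         else c(w[(1 - shift):nSamples], rep(w[nSamples], -shift))
  }
  w
}
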