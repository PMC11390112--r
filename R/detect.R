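#' @include AllClasses.R filter.R
NULL

#' Detection threshold from the RMS voltage of the session start
#'
#' The threshold is `thresholdMultiplier` (negative) times the root mean
#' square voltage of the first `rmsWindowS` seconds of the filtered
#' trace; when the session is shorter than the window, the whole trace
#' is used.
#'
#' @param filtered Filtered single-channel trace (microvolts).
#' @param fs Sampling rate, Hz.
#' @param config A [DetectionConfig-class].
#' @return Negative threshold in microvolts.
#' @examples
#' rmsThreshold(sin(2 * pi * seq(0, 1, by = 1 / 3e4)), 3e4) # ~ -4 / sqrt(2)
#' @export
rmsThreshold <- function(filtered, fs, config = detectionConfig()) {
  n <- min(length(filtered), round(config@rmsWindowS * fs))
  abortIf(n == 0L, "empty trace")
  rms <- sqrt(mean(filtered[seq_len(n)]^2))
  abortIf(rms == 0, "degenerate signal: RMS of the estimation window is zero")
  config@thresholdMultiplier * rms
}

#' Detect threshold-crossing events on a filtered trace
#'
#' For each downward crossing of the (negative) threshold, the event
#' time is the sample of peak depolarisation: the minimum of the trace
#' in the `postSamples`-long window starting at the crossing. After an
#' accepted event, further crossings within `deadTimeSamples` samples of
#' the event are ignored, so one spike yields one event. Events whose
#' 48-sample snippet window would overrun either end of the trace are
#' dropped.
#'
#' @param filtered Filtered single-channel trace (microvolts).
#' @param threshold Negative threshold (microvolts), e.g. from
#'   [rmsThreshold()].
#' @param config A [DetectionConfig-class].
#' @return Integer vector of trough sample indices (1-based), strictly
#'   increasing.
#' @export
detectEvents <- function(filtered, threshold, config = detectionConfig()) {
  abortIf(!(threshold < 0), "threshold must be negative")
  .detectScan(as.numeric(filtered), threshold, config@preSamples,
              config@postSamples, config@deadTimeSamples)
}

#' Extract trough-aligned snippets around detected events
#'
#' Each event yields 48 retained samples: the `preSamples` (16) points
#' preceding the trough, the trough itself, and the remaining
#' `postSamples - 1` (31) points after it, so the trough sits at column
#' 17. Values are converted to microvolts via `gainUv` when the trace is
#' in integer codes. Events too close to either edge are dropped.
#'
#' @param filtered Filtered single-channel trace.
#' @param events Trough sample indices from [detectEvents()].
#' @param config A [DetectionConfig-class].
#' @param electrode Electrode id recorded in the result.
#' @param fs Sampling rate, Hz.
#' @param gainUv Microvolts per unit of `filtered` (1 when the trace is
#'   already in microvolts).
#' @return A [SnippetMatrix-class] with all events initially accepted.
#' @export
extractSnippets <- function(filtered, events, config = detectionConfig(),
                            electrode = NA_integer_, fs = 30000,
                            gainUv = 1) {
  n <- length(filtered)
  keep <- events - config@preSamples >= 1L &
    events + config@postSamples - 1L <= n
  events <- as.integer(events[keep])
  width <- config@preSamples + config@postSamples
  snips <- matrix(numeric(), nrow = 0L, ncol = width)
  if (length(events)) {
    offs <- (-config@preSamples):(config@postSamples - 1L)
    idx <- outer(events, offs, "+")
    snips <- matrix(filtered[idx] * gainUv, nrow = length(events))
  }
  new("SnippetMatrix",
    electrode = as.integer(electrode), snippets = snips,
    eventTimes = events, accepted = rep(TRUE, length(events)), fs = fs
  )
}

# waveform width: separation of the two prominent peaks of the temporal
# derivative, taken as the global max and min of the first difference
waveformWidthMs <- function(snippet, fs) {
  d <- diff(snippet)
  abs(which.max(d) - which.min(d)) * 1000 / fs
}

#' Quality-control filtering of spike snippets
#'
#' Rejects snippets that are atypical of extracellular recordings from
#' cortical neurons: peak-to-trough amplitude above `amplitudeCapUv`
#' (default 300 uV), or waveform width above `widthCapMs` (default
#' 1 ms). Width is the separation between the two prominent peaks of the
#' temporal derivative, computed as the distance between the global
#' maximum and global minimum of the snippet's first difference.
#'
#' @param snippets A [SnippetMatrix-class] (microvolts).
#' @param config A [DetectionConfig-class].
#' @return The input with its `accepted` mask updated (previously
#'   rejected rows stay rejected).
#' @export
qcFilter <- function(snippets, config = detectionConfig()) {
  m <- snippets@snippets
  if (nrow(m) == 0L) return(snippets)
  qs <- .qcStats(m)
  widthsMs <- qs[, 2] * 1000 / snippets@fs
  snippets@accepted <- snippets@accepted &
    qs[, 1] <= config@amplitudeCapUv & widthsMs <= config@widthCapMs
  snippets
}

#' Per-electrode session summary: mean waveform and event rate
#'
#' Event rate is the number of accepted events divided by the effective
#' session duration. By default the effective duration runs from the
#' first accepted event on any electrode to the end of the session,
#' excluding inactive lead-in time; set `firstEventPolicy = "full"` to
#' divide by the full duration instead.
#'
#' @param snippetList List of [SnippetMatrix-class] objects, one per
#'   electrode.
#' @param durationS Recorded session duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param firstEventPolicy `"first_event"` (default) or `"full"`.
#' @return data.frame with one row per electrode: `electrode`,
#'   `n_accepted`, `rate` (events/s), `mean_defined` (FALSE when no
#'   accepted events), and 48 mean-waveform columns `w1..w48`
#'   (microvolts; NA when undefined).
#' @export
sessionSummary <- function(snippetList, durationS, fs = 30000,
                           firstEventPolicy = c("first_event", "full")) {
  abortIf(!(durationS > 0), "duration must be positive")
  firstEventPolicy <- match.arg(firstEventPolicy)
  firstTimes <- unlist(lapply(snippetList, function(s) {
    s@eventTimes[s@accepted]
  }))
  effective <- durationS
  if (firstEventPolicy == "first_event" && length(firstTimes)) {
    effective <- durationS - (min(firstTimes) - 1L) / fs
  }
  rows <- lapply(snippetList, function(s) {
    acc <- acceptedSnippets(s)
    mw <- if (nrow(acc)) colMeans(acc) else rep(NA_real_, 48L)
    out <- data.frame(
      electrode = s@electrode, n_accepted = nrow(acc),
      rate = nrow(acc) / effective, mean_defined = nrow(acc) > 0L
    )
    out[paste0("w", 1:48)] <- as.list(mw)
    out
  })
  do.call(rbind, rows)
}

#' Run the full detection chain on a multichannel recording
#'
#' For each channel: zero-phase high-pass filter, per-channel RMS
#' threshold, event detection, snippet extraction, and waveform QC.
#'
#' @param recording A [Recording-class].
#' @param config A [DetectionConfig-class].
#' @return List with `snippets` (list of [SnippetMatrix-class], named by
#'   electrode id) and `summary` (the [sessionSummary()] data.frame).
#' @examples
#' geom <- utahGeometry(3, 3, activeChannels = 1:9)
#' pop <- generatePopulation(geom, nNeurons = 9, seed = 1)
#' rec <- renderSession(pop, 1, durationS = 2, seed = 2)
#' det <- detectSession(rec)
#' det$summary[, c("electrode", "n_accepted", "rate")]
#' @export
detectSession <- function(recording, config = detectionConfig()) {
  geom <- recording@geometry
  chans <- activeChannels(geom)
  snippets <- vector("list", length(chans))
  names(snippets) <- chans
  for (i in seq_along(chans)) {
    trace <- as.numeric(recording@samples[i, ]) * recording@gainUv
    filt <- highpassFilter(trace, recording@fs, config)
    thr <- tryCatch(
      rmsThreshold(filt, recording@fs, config),
      error = function(e) NA_real_
    )
    if (is.na(thr)) {
      snippets[[i]] <- new("SnippetMatrix",
        electrode = chans[i],
        snippets = matrix(numeric(), 0L, 48L),
        eventTimes = integer(), accepted = logical(), fs = recording@fs
      )
      next
    }
    ev <- detectEvents(filt, thr, config)
    sm <- extractSnippets(filt, ev, config, electrode = chans[i],
                          fs = recording@fs)
    snippets[[i]] <- qcFilter(sm, config)
  }
  list(
    snippets = snippets,
    summary = sessionSummary(snippets, recording@durationS, recording@fs)
  )
}
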