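#' @include AllClasses.R io.R detect.R turnover.R groups.R physics.R
NULL

#' Default run configuration
#'
#' Every tunable of the pipeline is reachable from this nested list;
#' [readRunConfig()] merges a YAML file over these defaults. All
#' randomness flows from the named seeds -- no stage draws from the
#' global generator.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = "perilesion_out",
    simulate = list(
      enabled = TRUE,
      n_days = 13L,
      lesion_day = 4L,
      duration_s = 4,
      noise_sd_uv = 10,
      fs = 30000,
      gain_uv = 0.25,
      geometry = list(rows = 10L, cols = 10L, pitch_um = 400,
                      shank_um = 1000),
      neurons_per_electrode = 12L,
      rate_range = c(0.5, 20),
      trough_range_uv = c(65, 185),
      dist_range_um = c(50, 140),
      length_constant_um = 28,
      p_turnover = 0.05,
      amp_jitter = 0.05,
      lesion = list(
        enabled = TRUE,
        anode = 45L,
        cathode = 46L,
        current_ua = 150,
        duration_s = 45,
        volume_mm3 = 9.2, # sphere kill radius 1.3 mm: silences ~1/3 of neurons
        annulus_um = 700,
        annulus_amp_mult = 0.5,
        annulus_rate_mult = 0.8
      )
    ),
    detection = list(
      filter_order = 4L,
      filter_cutoff_hz = 250,
      threshold_multiplier = -4,
      rms_window_s = 60,
      pre_samples = 16L,
      post_samples = 32L,
      dead_time_samples = 48L,
      amplitude_cap_uv = 300,
      width_cap_ms = 1.0,
      first_event_policy = "first_event"
    ),
    turnover = list(
      n_sample = 1000L,
      min_events = 100L,
      k_max = 5L,
      gmm_restarts = 10L
    ),
    grouping = list(
      max_separation = 4L,
      acute_limit = 3L,
      late_window = c(4L, 7L),
      alpha = 0.05,
      n_comparisons = 3L,
      continuity = FALSE
    ),
    volume_fit = list(
      lesions_csv = NULL,
      current_ua = 180
    )
  )
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- mergeConfig(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; keys mirror [defaultRunConfig()].
#' @return Nested configuration list.
#' @export
readRunConfig <- function(path) {
  abortIf(!file.exists(path), sprintf("config file %s not found", path))
  mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

configDetection <- function(cfg) {
  d <- cfg$detection
  detectionConfig(
    filterOrder = d$filter_order, filterCutoffHz = d$filter_cutoff_hz,
    thresholdMultiplier = d$threshold_multiplier, rmsWindowS = d$rms_window_s,
    preSamples = d$pre_samples, postSamples = d$post_samples,
    deadTimeSamples = d$dead_time_samples,
    amplitudeCapUv = d$amplitude_cap_uv, widthCapMs = d$width_cap_ms
  )
}

validateConfig <- function(cfg) {
  abortIf(is.null(cfg$seed), "config must name a seed")
  if (isTRUE(cfg$simulate$enabled) && isTRUE(cfg$simulate$lesion$enabled)) {
    abortIf(is.null(cfg$simulate$lesion_day),
            "lesion_day is required when a lesion is simulated")
  }
  invisible(cfg)
}

stageLog <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[perilesion] %s", sprintf(fmt, ...)))
}

#' Run the full pipeline from a configuration
#'
#' Executes, as configured: simulate (recordings + ground truth) ->
#' detect (filter, threshold, snippets, QC, session summaries) ->
#' compare-days (waveform turnover, mixture fits, percent match) ->
#' turnover-test (group median tests) -> volume-fit (lesion volumes and
#' exponential model). All outputs are CSV (plus flat-binary
#' recordings/snippets) under `cfg$out_dir`, with a JSON manifest of
#' MD5 content hashes; a re-run with identical configuration and seeds
#' reproduces identical hashes.
#'
#' @param cfg Configuration list from [defaultRunConfig()] /
#'   [readRunConfig()].
#' @param verbose Log per-stage progress and counts to stderr.
#' @return Invisibly, a result bundle: list with `manifest` (file ->
#'   md5), `config`, `outputs` (paths), and the in-memory analysis
#'   results.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), verbose = TRUE) {
  validateConfig(cfg)
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  dcfg <- configDetection(cfg)

  sessionSnippets <- list()
  days <- integer()
  lesionDay <- cfg$simulate$lesion_day

  if (isTRUE(cfg$simulate$enabled)) {
    sc <- cfg$simulate
    geom <- utahGeometry(
      nRows = sc$geometry$rows, nCols = sc$geometry$cols,
      pitchUm = sc$geometry$pitch_um, shankUm = sc$geometry$shank_um
    )
    days <- seq_len(sc$n_days)
    pop <- generatePopulation(
      geom, nNeurons = sc$neurons_per_electrode * nChannels(geom),
      nDays = sc$n_days, seed = deriveSeed(cfg$seed, 1L),
      rateRange = sc$rate_range, troughRangeUv = sc$trough_range_uv,
      distRangeUm = sc$dist_range_um,
      lengthConstantUm = sc$length_constant_um,
      pTurnover = sc$p_turnover, ampJitter = sc$amp_jitter
    )
    if (isTRUE(sc$lesion$enabled)) {
      pop <- applyLesion(
        pop,
        lesionSpec(sc$lesion$anode, sc$lesion$cathode,
                   sc$lesion$current_ua, sc$lesion$duration_s,
                   dayOfLesion = sc$lesion_day),
        volumeModel = sc$lesion$volume_mm3,
        annulusUm = sc$lesion$annulus_um,
        annulusAmpMult = sc$lesion$annulus_amp_mult,
        annulusRateMult = sc$lesion$annulus_rate_mult
      )
    }
    writeGroundTruth(pop, file.path(outDir, "ground_truth.csv"))
    recDir <- file.path(outDir, "recordings")
    dir.create(recDir, showWarnings = FALSE)
    for (d in days) {
      rec <- renderSession(
        pop, d, durationS = sc$duration_s, noiseSdUv = sc$noise_sd_uv,
        fs = sc$fs, seed = deriveSeed(cfg$seed, 2L, d),
        gainUv = sc$gain_uv, lengthConstantUm = sc$length_constant_um
      )
      writeRecording(rec, file.path(recDir, sprintf("day_%02d.bin", d)))
      det <- detectSession(rec, dcfg)
      sessionSnippets[[as.character(d)]] <- det$snippets
      utils::write.csv(
        det$summary,
        file.path(outDir, sprintf("session_summary_day_%02d.csv", d)),
        row.names = FALSE
      )
      writeSnippetStore(det$snippets,
                        file.path(outDir, sprintf("snippets_day_%02d", d)))
      stageLog(verbose, "day %d: %d accepted events", d,
               sum(det$summary$n_accepted))
    }
    stageLog(verbose, "simulate+detect done (%.1f s)",
             as.numeric(Sys.time() - t0, units = "secs"))
  }

  results <- list()
  if (length(sessionSnippets) >= 3L && !is.null(lesionDay)) {
    tv <- cfg$turnover
    gp <- cfg$grouping
    ana <- turnoverAnalysis(
      sessionSnippets, days, lesionDay,
      nSample = tv$n_sample, minEvents = tv$min_events, kMax = tv$k_max,
      seed = deriveSeed(cfg$seed, 3L),
      maxSeparation = gp$max_separation, acuteLimit = gp$acute_limit,
      lateWindow = gp$late_window, alpha = gp$alpha,
      nComparisons = gp$n_comparisons
    )
    utils::write.csv(ana$pairComparisons,
                     file.path(outDir, "pair_comparisons.csv"),
                     row.names = FALSE)
    mixTab <- do.call(rbind, lapply(names(ana$mixtureFits), function(g) {
      f <- ana$mixtureFits[[g]]
      if (is.null(f)) return(NULL)
      data.frame(
        group = g, k = f@k, component = seq_len(f@k),
        weight = f@weights, mean = f@means, sd = f@sds,
        bic = f@bicByK$bic[f@k], match_component = f@matchComponent
      )
    }))
    utils::write.csv(mixTab, file.path(outDir, "mixture_fit.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$percentMatch,
                     file.path(outDir, "percent_match.csv"),
                     row.names = FALSE)
    utils::write.csv(ana$tests, file.path(outDir, "median_tests.csv"),
                     row.names = FALSE)
    results$turnover <- ana
    stageLog(verbose, "turnover analysis done: %d day pairs",
             nrow(ana$groups))
  }

  if (!is.null(cfg$volume_fit$lesions_csv)) {
    lesions <- readLesionTable(cfg$volume_fit$lesions_csv)
    vols <- lesionVolumes(lesions)
    utils::write.csv(vols, file.path(outDir, "volumes.csv"),
                     row.names = FALSE)
    sel <- vols$setting == "ex_vivo" &
      vols$current_uA == cfg$volume_fit$current_ua
    if (sum(sel) >= 3L) {
      fit <- fitExponential(vols$duration_s[sel] / 60,
                            vols$volume_mm3[sel], timeUnit = "min")
      utils::write.csv(
        data.frame(a = fit$a, b = fit$b, r_squared = fit$r_squared,
                   time_unit = fit$time_unit, n = fit$n),
        file.path(outDir, "exp_fit.csv"), row.names = FALSE
      )
      results$exponentialFit <- fit
    }
    results$volumes <- vols
    stageLog(verbose, "volume fit done")
  }

  files <- sort(list.files(outDir, recursive = TRUE, full.names = TRUE))
  manifest <- tools::md5sum(files)
  names(manifest) <- sub(paste0("^", outDir, "/?"), "", names(manifest))
  bundle <- list(
    manifest = manifest,
    config = cfg,
    outputs = files,
    results = results,
    version = as.character(utils::packageVersion("perilesion"))
  )
  jsonlite::write_json(
    list(version = bundle$version, files = as.list(manifest)),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE
  )
  stageLog(verbose, "pipeline complete (%.1f s)",
           as.numeric(Sys.time() - t0, units = "secs"))
  invisible(bundle)
}
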