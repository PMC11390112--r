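#' @include AllClasses.R geometry.R
NULL

metaPath <- function(path) paste0(path, ".meta")

#' Write / read a recording as flat binary plus sidecar metadata
#'
#' The binary holds little-endian 16-bit signed integer voltage codes in
#' channel-interleaved sample frames (all channels for sample 1, then
#' all channels for sample 2, ...). A plain-text sidecar
#' (`<path>.meta`, one `key value` pair per line) carries the sampling
#' metadata and array geometry. The round trip is lossless.
#'
#' @param recording A [Recording-class].
#' @param path Binary file path; the sidecar is written to
#'   `<path>.meta`.
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns a [Recording-class].
#' @examples
#' geom <- utahGeometry(2, 2, activeChannels = 1:4)
#' pop <- generatePopulation(geom, nNeurons = 4, seed = 1)
#' rec <- renderSession(pop, 1, durationS = 0.1, seed = 1)
#' f <- tempfile(fileext = ".bin")
#' writeRecording(rec, f)
#' identical(readRecording(f)@samples, rec@samples)
#' @export
writeRecording <- function(recording, path) {
  geom <- recording@geometry
  meta <- c(
    sprintf("fs %.10g", recording@fs),
    sprintf("n_channels %d", nrow(recording@samples)),
    sprintf("gain_uv %.10g", recording@gainUv),
    sprintf("duration_s %.10g", recording@durationS),
    sprintf("day_index %d", recording@dayIndex),
    sprintf("geometry_rows %d", geom@nRows),
    sprintf("geometry_cols %d", geom@nCols),
    sprintf("geometry_pitch_um %.10g", geom@pitchUm),
    sprintf("geometry_shank_um %.10g", geom@shankUm),
    sprintf("geometry_active %s",
            paste(activeChannels(geom), collapse = ","))
  )
  writeLines(meta, metaPath(path))
  con <- file(path, "wb")
  on.exit(close(con))
  # column-major storage of the channels x time matrix IS
  # channel-interleaved frame order
  writeBin(as.integer(recording@samples), con, size = 2L,
           endian = "little")
  invisible(path)
}

readSidecar <- function(path) {
  abortIf(!file.exists(metaPath(path)),
          sprintf("sidecar %s is missing", metaPath(path)))
  lines <- readLines(metaPath(path))
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(" .*$", "", lines)
  vals <- sub("^[^ ]+ ", "", lines)
  names(vals) <- keys
  need <- c("fs", "n_channels", "gain_uv", "duration_s", "day_index",
            "geometry_rows", "geometry_cols", "geometry_pitch_um",
            "geometry_shank_um", "geometry_active")
  missing <- setdiff(need, keys)
  abortIf(length(missing) > 0,
          sprintf("sidecar is missing key(s): %s",
                  paste(missing, collapse = ", ")))
  vals
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  vals <- readSidecar(path)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vals[[k]]))
    abortIf(is.na(v), sprintf("sidecar field %s is not numeric", k))
    v
  }
  fs <- num("fs")
  abortIf(!(fs > 0), "sidecar field fs must be positive")
  gain <- num("gain_uv")
  abortIf(!is.finite(gain) || !(gain > 0),
          "sidecar field gain_uv must be positive and finite")
  nCh <- as.integer(num("n_channels"))
  durS <- num("duration_s")
  geom <- utahGeometry(
    nRows = as.integer(num("geometry_rows")),
    nCols = as.integer(num("geometry_cols")),
    pitchUm = num("geometry_pitch_um"),
    shankUm = num("geometry_shank_um"),
    activeChannels = as.integer(strsplit(vals[["geometry_active"]], ",")[[1]])
  )
  abortIf(nCh != nChannels(geom),
          "sidecar field n_channels disagrees with geometry_active")

  nSamp <- as.integer(round(durS * fs))
  expectBytes <- 2 * nCh * nSamp
  actualBytes <- file.size(path)
  abortIf(is.na(actualBytes) || actualBytes != expectBytes,
          sprintf("binary length mismatch: expected %d bytes, found %s",
                  expectBytes, format(actualBytes)))
  con <- file(path, "rb")
  on.exit(close(con))
  codes <- readBin(con, "integer", n = nCh * nSamp, size = 2L,
                   signed = TRUE, endian = "little")
  new("Recording",
    samples = matrix(codes, nrow = nCh),
    fs = fs, gainUv = gain, durationS = durS,
    dayIndex = as.integer(num("day_index")), geometry = geom
  )
}

#' Write / read a per-electrode snippet store
#'
#' One flat binary of little-endian doubles per electrode
#' (`electrode_<id>.bin`, snippets stored row by row) plus a CSV index
#' (`events.csv`: electrode, event sample index, accepted flag) and a
#' per-electrode manifest (`index.csv`). Lossless round trip.
#'
#' @param snippetList List of [SnippetMatrix-class] objects.
#' @param dir Output directory (created if needed).
#' @return `writeSnippetStore` returns `dir` invisibly;
#'   `readSnippetStore` returns the list of [SnippetMatrix-class].
#' @export
writeSnippetStore <- function(snippetList, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- do.call(rbind, lapply(snippetList, function(s) {
    data.frame(electrode = s@electrode, n_events = length(s@eventTimes),
               fs = s@fs)
  }))
  utils::write.csv(idx, file.path(dir, "index.csv"), row.names = FALSE)
  ev <- do.call(rbind, lapply(snippetList, function(s) {
    if (!length(s@eventTimes)) return(NULL)
    data.frame(electrode = s@electrode, event_time = s@eventTimes,
               accepted = s@accepted)
  }))
  if (is.null(ev)) {
    ev <- data.frame(electrode = integer(), event_time = integer(),
                     accepted = logical())
  }
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  for (s in snippetList) {
    con <- file(file.path(dir, sprintf("electrode_%d.bin", s@electrode)),
                "wb")
    writeBin(as.numeric(t(s@snippets)), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname writeSnippetStore
#' @export
readSnippetStore <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  lapply(seq_len(nrow(idx)), function(i) {
    e <- idx$electrode[i]
    n <- idx$n_events[i]
    f <- file.path(dir, sprintf("electrode_%d.bin", e))
    con <- file(f, "rb")
    vals <- readBin(con, "numeric", n = n * 48L, size = 8L,
                    endian = "little")
    close(con)
    sel <- ev[ev$electrode == e, , drop = FALSE]
    new("SnippetMatrix",
      electrode = as.integer(e),
      snippets = matrix(vals, nrow = n, ncol = 48L, byrow = TRUE),
      eventTimes = as.integer(sel$event_time),
      accepted = as.logical(sel$accepted),
      fs = idx$fs[i]
    )
  })
}

#' Write the ground-truth neuron table (one row per neuron per day)
#'
#' @param population A [NeuronPopulation-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(population, path) {
  nb <- population@neurons
  eff <- population@dayEffects
  tab <- merge(
    eff,
    nb[, c("id", "x", "y", "z", "electrode", "rate", "alive",
           "lesion_amp_mult", "lesion_rate_mult")],
    by = "id", suffixes = c("", "_baseline")
  )
  tab <- tab[order(tab$day, tab$id), ]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a lesion parameter table
#'
#' Expected columns: `id`, `species`, `setting` (`ex_vivo` /
#' `in_vivo`), `current_uA`, `duration_s`, `geometry` (`cone` /
#' `sphere`), `radius_mm`, `height_mm` (may be empty), `damage_type`;
#' optionally `source` (`histology_slice` / `photo`; defaults to
#' `photo` when the height is missing).
#'
#' @param path CSV path.
#' @return data.frame with a `source` column filled in.
#' @export
readLesionTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "setting", "current_uA", "duration_s", "geometry",
            "radius_mm")
  missing <- setdiff(need, names(tab))
  abortIf(length(missing) > 0,
          sprintf("lesion table missing column(s): %s",
                  paste(missing, collapse = ", ")))
  if (is.null(tab$height_mm)) tab$height_mm <- NA_real_
  if (is.null(tab$source)) {
    tab$source <- ifelse(is.na(tab$height_mm), "photo", "histology_slice")
  }
  tab
}

#' Estimate volumes for every lesion in a table
#'
#' @param lesions data.frame from [readLesionTable()].
#' @return The table with a `volume_mm3` column appended.
#' @export
lesionVolumes <- function(lesions) {
  lesions$volume_mm3 <- vapply(seq_len(nrow(lesions)), function(i) {
    estimateVolume(
      lesions$radius_mm[i], lesions$height_mm[i],
      geometry = lesions$geometry[i], source = lesions$source[i]
    )$volume_mm3
  }, numeric(1))
  lesions
}
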