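#' @include AllClasses.R
NULL

#' Construct a Utah-array geometry
#'
#' Default geometry of the chronically implanted array: a 10 x 10 grid
#' (4 mm x 4 mm footprint) with 400 um inter-electrode pitch, 1 mm
#' shanks, and 96 wired channels -- the four corner sites are unwired.
#'
#' @param nRows,nCols Grid dimensions.
#' @param pitchUm Inter-electrode spacing, micrometres.
#' @param shankUm Shank length, micrometres; tips sit at this depth.
#' @param activeChannels Wired site ids (1-based, row-major). The default
#'   drops the four corners of the grid.
#' @return An [ArrayGeometry-class] object.
#' @examples
#' geom <- utahGeometry()
#' nChannels(geom) # 96
#' @export
utahGeometry <- function(nRows = 10L, nCols = 10L, pitchUm = 400,
                         shankUm = 1000, activeChannels = NULL) {
  nRows <- as.integer(nRows)
  nCols <- as.integer(nCols)
  if (is.null(activeChannels)) {
    all <- seq_len(nRows * nCols)
    corners <- c(
      1L, nCols, (nRows - 1L) * nCols + 1L, nRows * nCols
    )
    activeChannels <- setdiff(all, corners)
  }
  new("ArrayGeometry",
    nRows = nRows, nCols = nCols, pitchUm = pitchUm, shankUm = shankUm,
    activeChannels = as.integer(activeChannels)
  )
}

#' Electrode tip positions in the array frame
#'
#' Positions are in micrometres: x along columns, y along rows (both
#' starting at 0 for the first site), z the tip depth (= shank length).
#'
#' @param geometry An [ArrayGeometry-class].
#' @param channels Electrode ids; defaults to all active channels.
#' @return Numeric matrix with columns `x`, `y`, `z` and one row per
#'   channel (rownames = channel ids).
#' @examples
#' pos <- electrodePositions(utahGeometry())
#' dim(pos) # 96 x 3
#' @export
electrodePositions <- function(geometry, channels = activeChannels(geometry)) {
  abortIf(
    !all(channels %in% seq_len(geometry@nRows * geometry@nCols)),
    "channel ids outside the grid"
  )
  row <- (channels - 1L) %/% geometry@nCols
  col <- (channels - 1L) %% geometry@nCols
  out <- cbind(
    x = col * geometry@pitchUm,
    y = row * geometry@pitchUm,
    z = rep(geometry@shankUm, length(channels))
  )
  rownames(out) <- channels
  out
}

#' Diagonal span of a rectangular array footprint
#'
#' Euclidean diagonal of the array footprint: the largest separation
#' available when lesioning through electrodes on opposite corners. For
#' the 4 mm x 4 mm Utah array this is 5.66 mm.
#'
#' @param sideAMm,sideBMm Footprint side lengths, millimetres.
#' @return Diagonal length in millimetres.
#' @examples
#' arraySpan(4, 4) # 5.657
#' @export
arraySpan <- function(sideAMm, sideBMm) {
  abortIf(!(sideAMm > 0) || !(sideBMm > 0), "sides must be positive")
  sqrt(sideAMm^2 + sideBMm^2)
}
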