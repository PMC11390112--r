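#' @include AllClasses.R
NULL

#' Estimate a lesion volume from histology or photo measurements
#'
#' Cone volumes use `V = pi r^2 h / 3`; sphere volumes use
#' `V = 4/3 pi r^3` (any supplied height is ignored with a warning).
#' Measurements from a histology slice are assumed to bisect the
#' lesion, so radius and height are used directly. For photo-sourced
#' cones with no height measurement the height is taken equal to the
#' radius.
#'
#' @param radiusMm Lesion radius, millimetres (> 0).
#' @param heightMm Cone height, millimetres, or `NA` when unknown.
#' @param geometry `"cone"` or `"sphere"`.
#' @param source `"histology_slice"` or `"photo"`.
#' @return List with `geometry`, `radius_mm`, `height_mm` (NA for
#'   spheres), `volume_mm3`, `source`.
#' @examples
#' estimateVolume(1, 3, "cone")$volume_mm3           # pi
#' estimateVolume(0.75, geometry = "sphere")$volume_mm3 # 1.767
#' estimateVolume(0.5, geometry = "cone", source = "photo")$volume_mm3
#' @export
estimateVolume <- function(radiusMm, heightMm = NA_real_,
                           geometry = c("cone", "sphere"),
                           source = c("histology_slice", "photo")) {
  geometry <- match.arg(geometry)
  source <- match.arg(source)
  abortIf(!(radiusMm > 0), "radius must be positive")
  if (geometry == "sphere") {
    if (!is.na(heightMm)) {
      warning("height is ignored for spherical volumes")
    }
    vol <- 4 / 3 * pi * radiusMm^3
    heightMm <- NA_real_
  } else {
    if (is.na(heightMm)) {
      abortIf(source != "photo",
              "cone height required for histology-slice measurements")
      heightMm <- radiusMm # photo: height unknown, assumed equal to radius
    }
    abortIf(!(heightMm > 0), "height must be positive")
    vol <- pi * radiusMm^2 * heightMm / 3
  }
  list(
    geometry = geometry, radius_mm = radiusMm, height_mm = heightMm,
    volume_mm3 = vol, source = source
  )
}

#' Fit an exponential lesion volume-duration model
#'
#' Nonlinear least squares of `V = a exp(b t)` (fitted on the original
#' volume scale, not log-linearised; a log-linear regression only seeds
#' the start values). R-squared is `1 - SS_res / SS_tot` on the
#' original scale.
#'
#' @param durations Current durations (unit-tagged by `timeUnit`; the
#'   fitted `b` is per that unit and is never silently converted).
#' @param volumes Lesion volumes (> 0), same length.
#' @param timeUnit Label stored with the model (default `"min"`).
#' @return List of class `exponentialModel`: `a`, `b`, `r_squared`,
#'   `time_unit`, `n`.
#' @examples
#' t <- 0:3
#' fitExponential(t, 2 * exp(0.5 * t)) # recovers a = 2, b = 0.5, R2 = 1
#' @export
fitExponential <- function(durations, volumes, timeUnit = "min") {
  abortIf(length(durations) != length(volumes), "length mismatch")
  abortIf(length(durations) < 3L, "insufficient data: need >= 3 points")
  abortIf(any(volumes <= 0), "volumes must be positive")
  start <- stats::coef(stats::lm(log(volumes) ~ durations))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      volumes ~ a * exp(b * durations),
      start = list(a = exp(start[[1]]), b = start[[2]]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("exponential fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  cf <- stats::coef(fit)
  pred <- cf[["a"]] * exp(cf[["b"]] * durations)
  ssRes <- sum((volumes - pred)^2)
  ssTot <- sum((volumes - mean(volumes))^2)
  structure(
    list(
      a = cf[["a"]], b = cf[["b"]],
      r_squared = if (ssTot > 0) 1 - ssRes / ssTot else 1,
      time_unit = timeUnit, n = length(volumes)
    ),
    class = "exponentialModel"
  )
}

#' @export
print.exponentialModel <- function(x, ...) {
  cat(sprintf("Exponential volume model: V = %.4g * exp(%.4g t) [t in %s], R^2 = %.3f, n = %d\n",
              x$a, x$b, x$time_unit, x$r_squared, x$n))
  invisible(x)
}

#' Predict lesion volume from an exponential model
#'
#' @param model An `exponentialModel` (see [fitExponential()]), or a
#'   list with elements `a` and `b`.
#' @param t Duration(s), in the model's time unit.
#' @return Predicted volume(s) `a * exp(b * t)`.
#' @examples
#' m <- list(a = 5.4e-7, b = 5.6)
#' predictVolume(m, 0) # 5.4e-7
#' @export
predictVolume <- function(model, t) {
  abortIf(is.null(model$a) || is.null(model$b), "invalid model")
  model$a * exp(model$b * t)
}

#' Maximum electrode-pair impedance the lesioning device can drive
#'
#' With supply rails `vcc` and `vee` and a desired set current, Ohm's
#' law bounds the load impedance at `(vcc - vee) / current`. The
#' device's +/-450 V rails at 150 uA give 6 MOhm.
#'
#' @param vccV,veeV Positive and negative supply rails, volts.
#' @param setCurrentUa Desired output current, microamps (> 0).
#' @return Maximum load impedance in megaohms.
#' @examples
#' maxLoadImpedance(450, -450, 150) # 6
#' @export
maxLoadImpedance <- function(vccV = 450, veeV = -450, setCurrentUa = 150) {
  abortIf(!(setCurrentUa > 0), "set current must be positive")
  (vccV - veeV) / setCurrentUa # V / uA = MOhm
}

#' Parasitic parallel resistance implied by excess current
#'
#' A hypothesised parallel path to ground through the animal explains
#' current readings above the calibrated set value; Ohm's law on the
#' supply gives `R = supply / excess`. A 12 V supply with 10-20 uA
#' excess implies 1.2-0.6 MOhm. Negative excess indicates a capacitive
#' regime and is rejected rather than reported as a negative
#' resistance.
#'
#' @param supplyV Supply voltage, volts (default 12).
#' @param excessCurrentUa Current above the set value, microamps (> 0).
#' @return Parasitic resistance in megaohms.
#' @examples
#' parasiticResistance(12, 10) # 1.2
#' parasiticResistance(12, 20) # 0.6
#' @export
parasiticResistance <- function(supplyV = 12, excessCurrentUa) {
  abortIf(excessCurrentUa == 0, "excess current must be non-zero")
  abortIf(excessCurrentUa < 0,
          "negative excess: capacitive regime, no parallel resistance implied")
  supplyV / excessCurrentUa # V / uA = MOhm
}

#' Maximum voltage the device can deliver across the load
#'
#' Bounded by the supply rails: `vcc - vee` (900 V for +/-450 V).
#'
#' @param vccV,veeV Supply rails, volts.
#' @return Maximum output voltage, volts.
#' @examples
#' maxOutputVoltage(450, -450) # 900
#' @export
maxOutputVoltage <- function(vccV = 450, veeV = -450) {
  vccV - veeV
}
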