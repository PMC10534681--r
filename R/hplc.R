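#' HPLC calibration curve
#'
#' A linear detector-response calibration, \eqn{y = slope \cdot c +
#' intercept}, with its validated linear range and detection limits.
#' Defaults are the fluconazole UV assay line
#' (\eqn{y = 30676 x + 2843.9}, linear over 0.5--10 ug/mL, LOD
#' 0.007 ug/mL, LOQ 0.021 ug/mL).
#'
#' @param slope detector response per (ug/mL); must be positive.
#' @param intercept detector response at zero concentration.
#' @param range_low,range_high validated linear range (ug/mL).
#' @param lod,loq limits of detection and quantification (ug/mL),
#'   \code{0 < lod < loq}.
#' @return an object of class \code{"calibration_curve"}.
#' @export
calibration_curve <- function(slope = 30676, intercept = 2843.9,
                              range_low = 0.5, range_high = 10,
                              lod = 0.007, loq = 0.021) {
  if (!is.finite(slope) || slope <= 0) .fail("slope must be positive")
  if (!(lod > 0 && lod < loq)) .fail("limits must satisfy 0 < lod < loq")
  if (!(range_low > 0 && range_low < range_high))
    .fail("need 0 < range_low < range_high")
  if (loq > range_low)
    .fail("loq must not exceed the lower end of the linear range")
  structure(list(slope = slope, intercept = intercept,
                 range_low = range_low, range_high = range_high,
                 lod = lod, loq = loq),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration: response = %g * c + %g (c in ug/mL)\n",
              x$slope, x$intercept))
  cat(sprintf("  linear range %g-%g ug/mL; LOD %g, LOQ %g ug/mL\n",
              x$range_low, x$range_high, x$lod, x$loq))
  invisible(x)
}

#' Load a calibration curve from JSON
#'
#' @param path JSON file with fields \code{slope}, \code{intercept},
#'   \code{range_low}, \code{range_high}, \code{lod}, \code{loq};
#'   default is the packaged fluconazole curve.
#' @return a \code{calibration_curve}.
#' @export
calibration_from_json <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "flu_calibration.json",
                        package = "lacriflow", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(calibration_curve,
          cfg[c("slope", "intercept", "range_low", "range_high", "lod", "loq")])
}

#' Forward prediction: concentration to detector response
#'
#' @param curve a [calibration_curve()].
#' @param concentration ug/mL.
#' @return predicted peak area (response units).
#' @export
concentration_to_area <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  curve$slope * concentration + curve$intercept
}

#' Inverse prediction with LOD/LOQ flagging
#'
#' Back-calculates concentration from peak area,
#' \eqn{c = (area - intercept) / slope}, and flags it against the
#' assay limits.  The flag partitions \eqn{[0, \infty)} with
#' boundaries closed on the informative side: \code{c < lod} is
#' \code{not_detected} (reported as 0 so downstream statistics stay
#' defined), \code{lod <= c < loq} is
#' \code{detected_not_quantifiable}, \code{loq <= c <= range_high} is
#' \code{quantifiable}.  Above the linear range the inversion is an
#' extrapolation and errors unless \code{allow_extrapolation = TRUE},
#' in which case the value is returned flagged \code{out_of_range}.
#'
#' @param curve a [calibration_curve()].
#' @param area detector response(s); must be finite.
#' @param allow_extrapolation permit concentrations above
#'   \code{range_high} (flagged \code{out_of_range}).
#' @return a \code{data.frame} with columns \code{area},
#'   \code{conc_ug_per_mL} and \code{flag}.
#' @export
area_to_concentration <- function(curve, area, allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(area))) .fail("area must be finite")
  conc <- (area - curve$intercept) / curve$slope
  conc[conc < 0] <- 0
  # a 1e-9 relative guard keeps inverse-predicted values that sit exactly on
  # a limit from falling below it through float cancellation
  at_least <- function(x, b) x >= b * (1 - 1e-9)
  flag <- ifelse(!at_least(conc, curve$lod), "not_detected",
          ifelse(!at_least(conc, curve$loq), "detected_not_quantifiable",
          ifelse(conc <= curve$range_high * (1 + 1e-9),
                 "quantifiable", "out_of_range")))
  if (!allow_extrapolation && any(flag == "out_of_range"))
    .fail("back-calculated concentration above the linear range (",
          curve$range_high, " ug/mL); dilute the sample or set ",
          "allow_extrapolation = TRUE")
  conc[flag == "not_detected"] <- 0
  data.frame(area = area, conc_ug_per_mL = conc, flag = flag)
}

#' Drug amount recovered from a tissue extraction
#'
#' Converts an extract concentration to total drug amount,
#' \eqn{amount = c \times volume}, and — when the diffusional area is
#' given — to amount per unit area.  Defaults follow the corneal
#' workup: 5 mL extraction volume and a 1.0 cm2 diffusional area for
#' Franz-cell mounts.
#'
#' @param concentration extract concentration (ug/mL).
#' @param extraction_volume extraction volume (mL), positive.
#' @param diffusional_area exposed tissue area (cm2), positive, or
#'   \code{NULL} to skip the per-area column.
#' @return a \code{data.frame} with \code{amount_ug} and (if area
#'   given) \code{amount_ug_per_cm2}.
#' @export
tissue_amount <- function(concentration, extraction_volume = 5,
                          diffusional_area = NULL) {
  if (!is.finite(extraction_volume) || extraction_volume <= 0)
    .fail("extraction_volume must be positive")
  out <- data.frame(amount_ug = concentration * extraction_volume)
  if (!is.null(diffusional_area)) {
    if (!is.finite(diffusional_area) || diffusional_area <= 0)
      .fail("diffusional_area must be positive")
    out$amount_ug_per_cm2 <- out$amount_ug / diffusional_area
  }
  out
}

#' Batch inverse prediction from a sample table
#'
#' Reads (or takes) a table of \code{sample_id, area}, inverts each
#' response through the curve and appends the recovered tissue amount.
#'
#' @param samples a \code{data.frame} with columns \code{sample_id}
#'   and \code{area}, or a path to such a CSV.
#' @param curve a [calibration_curve()].
#' @param extraction_volume mL used for the tissue extraction.
#' @param allow_extrapolation passed to [area_to_concentration()].
#' @return a \code{data.frame} with columns \code{sample_id},
#'   \code{conc_ug_per_mL}, \code{flag}, \code{amount_ug}.
#' @export
quantify_batch <- function(samples, curve = calibration_curve(),
                           extraction_volume = 5,
                           allow_extrapolation = FALSE) {
  if (is.character(samples)) samples <- utils::read.csv(samples)
  missing <- setdiff(c("sample_id", "area"), names(samples))
  if (length(missing))
    .fail("sample table lacks column(s): ", paste(missing, collapse = ", "))
  inv <- area_to_concentration(curve, samples$area, allow_extrapolation)
  data.frame(sample_id = samples$sample_id,
             conc_ug_per_mL = inv$conc_ug_per_mL,
             flag = inv$flag,
             amount_ug = inv$conc_ug_per_mL * extraction_volume)
}
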