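#' Linear calibration curve
#'
#' Container for a per-analyte unweighted least-squares calibration
#' `area = slope * conc + intercept` with its Pearson correlation
#' coefficient, fitted range and detection/quantitation limits.
#'
#' @param analyte Analyte id.
#' @param slope,intercept Fitted coefficients (slope > 0).
#' @param r Pearson correlation coefficient of (conc, area).
#' @param range Length-2 numeric, `c(low, high)` in ug/mL, `low < high`.
#' @param lod,loq Limits of detection / quantitation (ug/mL), `lod < loq`
#'   when both present.
#' @param n Number of calibration points (>= 3).
#' @return A `calibration_curve` list.
#' @export
calibration_curve <- function(analyte, slope, intercept, r, range,
                              lod = NA_real_, loq = NA_real_, n = 3L) {
  check_that(slope > 0, "calibration slope must be > 0 (got %.4g)", slope)
  check_that(n >= 3, "a calibration needs at least 3 points")
  check_that(length(range) == 2 && range[1] < range[2],
             "range must be c(low, high) with low < high")
  if (is.finite(lod) && is.finite(loq)) {
    check_that(lod < loq, "LOD must be below LOQ")
  }
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r = r, range = as.numeric(range), lod = lod, loq = loq,
                 n = as.integer(n)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: area = %.5g conc %+.5g (R = %.4f, %g-%g ug/mL, n = %d)\n",
              x$analyte, x$slope, x$intercept, x$r, x$range[1], x$range[2], x$n))
  invisible(x)
}

#' Fit an unweighted linear calibration
#'
#' Ordinary (unweighted) least squares of peak area on concentration,
#' with the Pearson correlation coefficient as the linearity measure and
#' the observed concentration span as the linear range.
#'
#' @param concs Concentrations, ug/mL (>= 3 distinct values).
#' @param areas Peak areas, same length.
#' @param analyte Analyte id recorded on the curve.
#' @param noise_sd_area Optional area-equivalent noise SD; when given,
#'   LOD/LOQ are filled via [lod_loq()].
#' @return A [calibration_curve()].
#' @export
#' @examples
#' x <- c(2, 20, 40, 60, 80, 100)
#' fit_calibration(x, 86.712 * x - 2.351, analyte = "PQ-6")
fit_calibration <- function(concs, areas, analyte = NA_character_,
                            noise_sd_area = NULL) {
  check_that(length(concs) == length(areas), "concs and areas differ in length")
  check_that(length(unique(concs)) >= 3,
             "need at least 3 distinct concentrations")
  xbar <- mean(concs); ybar <- mean(areas)
  sxx <- sum((concs - xbar)^2)
  check_that(sxx > 0, "all concentrations identical")
  slope <- sum((concs - xbar) * (areas - ybar)) / sxx
  intercept <- ybar - slope * xbar
  r <- stats::cor(concs, areas)
  curve <- calibration_curve(analyte, slope, intercept, r,
                             range = range(concs), n = length(concs))
  if (!is.null(noise_sd_area)) {
    ll <- lod_loq(curve, noise_sd_area)
    curve$lod <- ll[["lod"]]; curve$loq <- ll[["loq"]]
  }
  curve
}

#' External-standard quantitation
#'
#' Inverts the calibration: `conc = (area - intercept) / slope`. Values
#' outside the fitted range are returned but flagged through the
#' `out_of_range` attribute, mirroring how a chromatography data system
#' reports extrapolated results.
#'
#' @param curve A [calibration_curve()].
#' @param area Peak area(s).
#' @return Numeric concentration(s), ug/mL, with logical attribute
#'   `out_of_range`.
#' @export
#' @examples
#' cal <- load_fixture("calibration")
#' esm_quantify(cal[["PQ-6"]], 4333.25)
esm_quantify <- function(curve, area) {
  check_that(inherits(curve, "calibration_curve"),
             "curve must be a calibration_curve")
  conc <- (area - curve$intercept) / curve$slope
  structure(conc,
            out_of_range = conc < curve$range[1] | conc > curve$range[2])
}

#' Signal-to-noise detection and quantitation limits
#'
#' LOD and LOQ are the concentrations whose peak would stand 3 and 10
#' noise SDs above the baseline. By the signal-above-baseline convention
#' the intercept is ignored by default (`lod = 3 noise / slope`,
#' `loq = 10 noise / slope`, so `loq / lod = 10/3` exactly); with
#' `use_intercept = TRUE` the full inverse `(k noise - intercept) /
#' slope` is used, floored at zero.
#'
#' @param curve A [calibration_curve()].
#' @param noise_sd_area Baseline noise SD expressed in area-equivalent
#'   units (> 0); for a peak of nominal half-height width `w` a height
#'   noise `s_h` converts as `s_h * w * 1.064` (Gaussian area/height
#'   ratio).
#' @param use_intercept Include the calibration intercept (default
#'   `FALSE`).
#' @return Named numeric `c(lod =, loq =)`, ug/mL.
#' @export
lod_loq <- function(curve, noise_sd_area, use_intercept = FALSE) {
  check_that(noise_sd_area > 0, "noise SD must be > 0")
  b <- if (use_intercept) curve$intercept else 0
  lod <- max(0, (3 * noise_sd_area - b) / curve$slope)
  loq <- max(0, (10 * noise_sd_area - b) / curve$slope)
  c(lod = lod, loq = loq)
}

#' Fit the full mixed-standard calibration set
#'
#' Processes a simulated (or imported) standard series into per-analyte
#' calibration curves: each chromatogram is reduced to a peak table and
#' the assigned areas are regressed on the known level concentrations.
#'
#' @param series List of [injection_spec()]s (see
#'   [make_standard_series()]).
#' @param chroms Optional pre-simulated chromatograms matching `series`;
#'   simulated on the fly otherwise.
#' @param response,profile Forward model used when simulating.
#' @param min_snr Detection threshold.
#' @return Named list of [calibration_curve()]s, one per analyte, each
#'   with LOD/LOQ filled from the profile noise when it is positive.
#' @export
calibrate_series <- function(series,
                             chroms = NULL,
                             response = default_response_model(),
                             profile = instrument_profile(),
                             min_snr = 10) {
  if (is.null(chroms)) {
    chroms <- lapply(series, simulate_injection, response = response,
                     profile = profile)
  }
  tables <- lapply(chroms, process_chromatogram, min_snr = min_snr)
  curves <- lapply(analytes(), function(a) {
    concs <- vapply(series, function(s) s$conc[[a]], numeric(1))
    area <- vapply(tables, function(tb) {
      i <- match(a, tb$analyte)
      if (is.na(i)) NA_real_ else tb$area[i]
    }, numeric(1))
    keep <- is.finite(area)
    check_that(sum(keep) >= 3, "analyte %s detected at fewer than 3 levels", a)
    noise_area <- if (profile$noise_sd > 0) {
      profile$noise_sd * profile$width_half[[a]] * 1.064
    } else NULL
    fit_calibration(concs[keep], area[keep], analyte = a,
                    noise_sd_area = noise_area)
  })
  stats::setNames(curves, analytes())
}
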