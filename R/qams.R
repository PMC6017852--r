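#' Relative correction factor from one standard level
#'
#' `f = (A_s / C_s) / (A_x / C_x)`: the ratio of the reference marker's
#' response factor (area per concentration) to the analyte's, measured
#' from a mixed standard where both true concentrations are known.
#'
#' @param A_s,C_s Reference (PQ-6) peak area and concentration (> 0).
#' @param A_x,C_x Analyte peak area and concentration (> 0).
#' @return The relative correction factor (dimensionless, > 0).
#' @export
#' @examples
#' rcf_single_level(A_s = 4333.25, C_s = 50, A_x = 1008.0, C_x = 25)
rcf_single_level <- function(A_s, C_s, A_x, C_x) {
  check_that(all(c(A_s, C_s, A_x, C_x) > 0),
             "all areas and concentrations must be > 0")
  (A_s / C_s) / (A_x / C_x)
}

#' Aggregate per-level relative correction factors
#'
#' @param levels Either a named numeric vector of per-level `f` values,
#'   or a data frame with columns `A_s`, `C_s`, `A_x`, `C_x` (and
#'   optionally `level`) from which they are computed; >= 2 levels.
#' @param analyte Analyte id recorded on the estimate.
#' @return An `rcf_estimate`: list with `analyte`, `levels` (named
#'   per-level f), `mean_f` (arithmetic mean) and `rsd_pct`
#'   (100 x sample SD / mean).
#' @export
#' @examples
#' rcf_estimate(c(C1 = 2.174, C2 = 2.141, C3 = 2.204,
#'                C4 = 2.221, C5 = 2.146, C6 = 2.084), "PQ-1")
rcf_estimate <- function(levels, analyte = NA_character_) {
  if (is.data.frame(levels)) {
    f <- mapply(rcf_single_level, levels$A_s, levels$C_s,
                levels$A_x, levels$C_x)
    names(f) <- if ("level" %in% names(levels)) levels$level else
      paste0("C", seq_along(f))
    levels <- f
  }
  check_that(is.numeric(levels) && length(levels) >= 2,
             "need at least 2 levels")
  check_that(all(levels > 0), "all f values must be > 0")
  if (is.null(names(levels))) names(levels) <- paste0("C", seq_along(levels))
  m <- mean(levels)
  structure(list(analyte = analyte, levels = levels, mean_f = m,
                 rsd_pct = 100 * stats::sd(levels) / m),
            class = "rcf_estimate")
}

#' @export
print.rcf_estimate <- function(x, ...) {
  cat(sprintf("<rcf_estimate> %s: mean f = %.4g, RSD = %.2g%% over %d levels\n",
              x$analyte, x$mean_f, x$rsd_pct, length(x$levels)))
  invisible(x)
}

#' Single-marker quantitation of one analyte
#'
#' Quantifies an analyte from its peak area, the reference marker's
#' in-run area and concentration, and the pre-established relative
#' correction factor. The default `form = "consistent"` uses
#' `C_x = f_x (C_s / A_s) A_x`, the exact algebraic inverse of the RCF
#' definition (so `qams_quantify(rcf_single_level(...))` round-trips to
#' machine precision). The historical printed form that divides by `f_x`
#' instead is available as `form = "printed"` for comparison only; it is
#' not self-consistent with the RCF definition.
#'
#' @param A_x Analyte peak area (> 0).
#' @param A_s,C_s Reference peak area and concentration (> 0).
#' @param f_x Relative correction factor (> 0).
#' @param form `"consistent"` (default) or `"printed"`.
#' @return Concentration, ug/mL.
#' @export
#' @examples
#' f <- rcf_single_level(4333.25, 50, 1008.0, 25)
#' qams_quantify(A_x = 1008.0, A_s = 4333.25, C_s = 50, f_x = f)  # 25
qams_quantify <- function(A_x, A_s, C_s, f_x,
                          form = c("consistent", "printed")) {
  form <- match.arg(form)
  check_that(all(c(A_x, A_s, C_s, f_x) > 0), "all inputs must be > 0")
  if (form == "consistent") f_x * (C_s / A_s) * A_x
  else (A_x * C_s) / (A_s * f_x)
}

#' Quantify a whole run from the single PQ-6 marker
#'
#' True single-marker operation: the reference concentration comes from
#' the same run's PQ-6 peak via its own calibration curve, and every
#' other analyte is scaled from the in-run PQ-6 response through its
#' RCF. Alternatively an external single-point PQ-6 standard may supply
#' the reference response via `external_reference`.
#'
#' @param table A `peak_table` (see [assign_analytes()]) with PQ-6
#'   assigned.
#' @param pq6_curve The PQ-6 [calibration_curve()].
#' @param rcfs Named list of [rcf_estimate()]s (or named numeric mean f
#'   values) for the five non-reference analytes.
#' @param form Passed to [qams_quantify()].
#' @param external_reference Optional `list(A_s =, C_s =)` from an
#'   external PQ-6 standard run; by default the in-run peak is used.
#' @return Named numeric of concentrations over all six analytes, ug/mL;
#'   analytes without a peak (or without an RCF) are `NA`, not zero.
#' @export
single_marker_sample_quant <- function(table, pq6_curve, rcfs,
                                       form = c("consistent", "printed"),
                                       external_reference = NULL) {
  form <- match.arg(form)
  ref_i <- match(REFERENCE_ANALYTE, table$analyte)
  if (is.na(ref_i)) stop("reference peak not found", call. = FALSE)
  f_of <- function(x) if (inherits(x, "rcf_estimate")) x$mean_f else as.numeric(x)
  out <- stats::setNames(rep(NA_real_, 6), analytes())
  A6 <- table$area[ref_i]
  out[REFERENCE_ANALYTE] <- as.numeric(esm_quantify(pq6_curve, A6))
  ref <- if (is.null(external_reference)) {
    list(A_s = A6, C_s = out[[REFERENCE_ANALYTE]])
  } else external_reference
  for (a in setdiff(analytes(), REFERENCE_ANALYTE)) {
    i <- match(a, table$analyte)
    if (is.na(i) || is.null(rcfs[[a]])) next
    out[a] <- qams_quantify(table$area[i], ref$A_s, ref$C_s,
                            f_of(rcfs[[a]]), form = form)
  }
  out
}

#' Summarise an RCF robustness grid
#'
#' Grand mean, sample SD and RSD of the relative correction factors over
#' all instrument x column cells.
#'
#' @param grid Data frame with columns `instrument`, `column` and one
#'   numeric column per analyte (as returned by
#'   `load_fixture("robustness")`), or a plain cells x analytes numeric
#'   matrix; >= 2 cells, all values > 0.
#' @return Data frame: `analyte`, `mean_f`, `sd_f`, `rsd_pct`.
#' @export
#' @examples
#' robustness_summary(load_fixture("robustness"))
robustness_summary <- function(grid) {
  if (is.data.frame(grid)) {
    vals <- as.matrix(grid[setdiff(names(grid), c("instrument", "column"))])
  } else {
    vals <- as.matrix(grid)
  }
  check_that(nrow(vals) >= 2, "need at least 2 grid cells")
  check_that(is.numeric(vals) && all(vals > 0), "all cells must be positive")
  data.frame(
    analyte = colnames(vals),
    mean_f = colMeans(vals),
    sd_f = apply(vals, 2, stats::sd),
    rsd_pct = 100 * apply(vals, 2, stats::sd) / colMeans(vals),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Compare ESM and QAMS quantitation batch-wise
#'
#' Per-cell pair SD (the sample SD of the two determinations,
#' `|ESM - QAMS| / sqrt(2)`) and a per-analyte two-tailed paired t-test
#' across samples. No multiplicity correction is applied: each analyte
#' is reported separately.
#'
#' @param esm,qams Two [batch_content_matrix] objects with identical
#'   samples and analytes.
#' @param conf_level Confidence level recorded for reference (the test
#'   is two-tailed at `1 - conf_level`).
#' @return A `quant_comparison`: list with `pair_sd` (samples x analytes
#'   matrix), `mean_diff`, `p_value` (named per analyte; exactly-equal
#'   columns give p = 1), `n`, `alpha`.
#' @export
compare_methods <- function(esm, qams, conf_level = 0.95) {
  if (!identical(dim(esm), dim(qams)) ||
      !identical(dimnames(esm), dimnames(qams))) {
    stop("shape mismatch between ESM and QAMS matrices: ESM is ",
         nrow(esm), " x ", ncol(esm), " [",
         paste(colnames(esm), collapse = ","), "], QAMS is ",
         nrow(qams), " x ", ncol(qams), " [",
         paste(colnames(qams), collapse = ","), "]", call. = FALSE)
  }
  pair_sd <- abs(esm - qams) / sqrt(2)
  p <- vapply(colnames(esm), function(a) {
    d <- esm[, a] - qams[, a]
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    stats::t.test(esm[, a], qams[, a], paired = TRUE,
                  conf.level = conf_level)$p.value
  }, numeric(1))
  structure(
    list(pair_sd = unclass(pair_sd),
         mean_diff = colMeans(esm - qams),
         p_value = p, n = nrow(esm), alpha = 1 - conf_level),
    class = "quant_comparison"
  )
}

#' @export
print.quant_comparison <- function(x, ...) {
  cat(sprintf("<quant_comparison> %d sample pairs\n", x$n))
  print(data.frame(analyte = names(x$p_value),
                   mean_diff = unname(x$mean_diff),
                   p_two_tailed = unname(x$p_value), row.names = NULL))
  invisible(x)
}

#' Build a simulate-and-quantify pipeline handle
#'
#' Calibrates the system once (noiseless mixed-standard series under the
#' given response/profile: PQ-6 calibration curve plus RCFs for the five
#' co-existing analytes) and returns a function that maps an
#' [injection_spec()] to its six QAMS concentrations. Used by the
#' recovery test and the end-to-end parameter-recovery checks.
#'
#' @param response,profile Forward model.
#' @param min_snr Detection threshold.
#' @param form Passed to [qams_quantify()].
#' @return `list(quantify = function(spec), curves =, rcfs =)`.
#' @export
build_qams_pipeline <- function(response = default_response_model(),
                                profile = instrument_profile(),
                                min_snr = 10,
                                form = "consistent") {
  calm_profile <- profile
  calm_profile$noise_sd <- 0
  calm_profile$drift <- 0
  series <- make_standard_series(response)
  chroms <- lapply(series, simulate_injection, response = response,
                   profile = calm_profile)
  tables <- lapply(chroms, process_chromatogram, min_snr = min_snr)
  curves <- calibrate_series(series, chroms = chroms, response = response,
                             profile = calm_profile, min_snr = min_snr)
  rcfs <- lapply(setdiff(analytes(), REFERENCE_ANALYTE), function(a) {
    f <- vapply(seq_along(series), function(i) {
      tb <- tables[[i]]
      s <- match(REFERENCE_ANALYTE, tb$analyte)
      x <- match(a, tb$analyte)
      check_that(!is.na(s) && !is.na(x),
                 "analyte %s or reference missing at level %d", a, i)
      rcf_single_level(tb$area[s], series[[i]]$conc[[REFERENCE_ANALYTE]],
                       tb$area[x], series[[i]]$conc[[a]])
    }, numeric(1))
    rcf_estimate(stats::setNames(f, names(series)), analyte = a)
  })
  names(rcfs) <- setdiff(analytes(), REFERENCE_ANALYTE)
  quantify <- function(spec) {
    ch <- simulate_injection(spec, response, profile)
    tb <- process_chromatogram(ch, min_snr = min_snr)
    single_marker_sample_quant(tb, curves[[REFERENCE_ANALYTE]], rcfs,
                               form = form)
  }
  list(quantify = quantify, curves = curves, rcfs = rcfs)
}
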