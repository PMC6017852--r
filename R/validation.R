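#' Relative standard deviation
#'
#' `100 x sample SD / mean` with the n-1 denominator, the dispersion
#' statistic used throughout the validation and RCF summaries.
#'
#' @param values Numeric, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(2.174, 2.141, 2.204, 2.221, 2.146, 2.084))  # 2.3
rsd <- function(values) {
  check_that(length(values) >= 2, "need at least 2 values")
  m <- mean(values)
  check_that(m != 0, "mean must be nonzero")
  100 * stats::sd(values) / m
}

# replicate designs of the validation protocol
VALIDATION_DESIGNS <- c(stability = 5L, precision = 6L,
                        repeatability = 6L, reproducibility = 12L)

#' Replicate-based validation assessment
#'
#' Computes the RSDs of the relative retention times (RRT) and relative
#' peak areas (RPA) of every assigned analyte across a set of replicate
#' peak tables, the statistic used for the stability (n = 5, repeated
#' injection of one solution over 24 h), precision (n = 6 successive
#' injections), repeatability (n = 6 duplicate preparations) and
#' reproducibility (n = 12 duplicates across instruments/analysts)
#' criteria. The PQ-6 reference rows are exactly zero by construction:
#' RRT and RPA are ratios to the reference peak itself.
#'
#' @param tables List of `peak_table`s, one per replicate.
#' @param criterion One of `"stability"`, `"precision"`,
#'   `"repeatability"`, `"reproducibility"`.
#' @param n Expected replicate count; defaults to the criterion's design
#'   (5/6/6/12) and must match `length(tables)`.
#' @return Data frame: `analyte`, `criterion`, `n`, `rsd_rrt_pct`,
#'   `rsd_rpa_pct`.
#' @export
replicate_assessment <- function(tables,
                                 criterion = c("stability", "precision",
                                               "repeatability",
                                               "reproducibility"),
                                 n = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(n)) n <- VALIDATION_DESIGNS[[criterion]]
  check_that(length(tables) == n,
             "%s design expects %d replicates, got %d",
             criterion, n, length(tables))
  present <- Reduce(union, lapply(tables, function(tb) stats::na.omit(tb$analyte)))
  present <- analytes()[analytes() %in% present]
  for (i in seq_along(tables)) {
    miss <- setdiff(present, tables[[i]]$analyte)
    check_that(!length(miss), "replicate %d is missing analyte(s): %s",
               i, paste(miss, collapse = ", "))
  }
  rows <- lapply(present, function(a) {
    rrt <- vapply(tables, function(tb) tb$rrt[match(a, tb$analyte)], numeric(1))
    rpa <- vapply(tables, function(tb) tb$rpa[match(a, tb$analyte)], numeric(1))
    data.frame(analyte = a, criterion = criterion, n = n,
               rsd_rrt_pct = rsd(rrt), rsd_rpa_pct = rsd(rpa),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Standard-addition recovery test
#'
#' Spikes a base sample at several levels, re-runs the full
#' quantitation pipeline, and reports the marginal recovery
#' `100 (found - base_found) / added` per analyte (the conventional
#' standard-addition convention; `convention = "total"` reports
#' `100 found_spiked / (base_found + added)` instead). Spike levels
#' default to 80/100/120% of the base content; with `replicates = 2`
#' per level this gives the customary n = 6 recoveries per analyte.
#'
#' @param base An [injection_spec()] holding the base (unspiked) true
#'   concentrations.
#' @param spike_levels Positive spike fractions of the base content.
#' @param replicates Replicates per spike level.
#' @param pipeline A quantitation handle: function mapping an
#'   [injection_spec()] to named found concentrations (see
#'   [build_qams_pipeline()]); defaults to the default-model QAMS
#'   pipeline.
#' @param seed Base seed for the spiked injections.
#' @param added Optional list (one named numeric per spike level) of
#'   absolute added concentrations, required when the base is a blank
#'   (fractions of zero add nothing).
#' @param convention `"marginal"` (default) or `"total"`.
#' @return List with `per_analyte` (`analyte`, `n`, `mean_pct`,
#'   `rsd_pct`) and `per_level` (`analyte`, `level`, `mean_pct`)
#'   aggregations.
#' @export
recovery_test <- function(base, spike_levels = c(0.8, 1.0, 1.2),
                          replicates = 2,
                          pipeline = NULL, seed = 1, added = NULL,
                          convention = c("marginal", "total")) {
  convention <- match.arg(convention)
  check_that(all(spike_levels > 0), "added amount 0: spike fractions must be > 0")
  if (is.null(pipeline)) pipeline <- build_qams_pipeline()$quantify
  if (is.function(pipeline) == FALSE && !is.null(pipeline$quantify)) {
    pipeline <- pipeline$quantify
  }
  blank_base <- all(base$conc == 0)
  if (is.null(added)) {
    check_that(!blank_base,
               "added amount 0: give absolute `added` levels for a blank base")
    added <- lapply(spike_levels, function(fr) fr * base$conc)
  }
  check_that(length(added) == length(spike_levels),
             "one added-concentration vector per spike level required")
  found_base <- if (blank_base) {
    stats::setNames(rep(0, 6), analytes())
  } else {
    b <- base
    b$seed <- seed
    pipeline(b)
  }
  rec <- list()
  run <- 0L
  for (li in seq_along(spike_levels)) {
    add <- stats::setNames(rep(0, 6), analytes())
    add[names(added[[li]])] <- added[[li]]
    check_that(any(add > 0), "added amount 0 at level %d", li)
    for (ri in seq_len(replicates)) {
      run <- run + 1L
      spec <- injection_spec(base$conc + add, label = "sample",
                             replicate = ri, seed = seed + 131L * run)
      found <- pipeline(spec)
      pct <- stats::setNames(rep(NA_real_, 6), analytes())
      for (a in analytes()) {
        if (add[[a]] <= 0 || is.na(found[[a]])) next
        pct[a] <- if (convention == "marginal") {
          100 * (found[[a]] - found_base[[a]]) / add[[a]]
        } else {
          100 * found[[a]] / (found_base[[a]] + add[[a]])
        }
      }
      rec[[run]] <- data.frame(analyte = analytes(), level = li,
                               recovery_pct = unname(pct),
                               stringsAsFactors = FALSE)
    }
  }
  all_rec <- do.call(rbind, rec)
  all_rec <- all_rec[is.finite(all_rec$recovery_pct), ]
  per_analyte <- do.call(rbind, lapply(split(all_rec, all_rec$analyte), function(d) {
    data.frame(analyte = d$analyte[1], n = nrow(d),
               mean_pct = mean(d$recovery_pct),
               rsd_pct = if (nrow(d) >= 2) rsd(d$recovery_pct) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_level <- stats::aggregate(recovery_pct ~ analyte + level, all_rec, mean)
  names(per_level)[3] <- "mean_pct"
  rownames(per_analyte) <- NULL
  list(per_analyte = per_analyte[order(match(per_analyte$analyte, analytes())), ],
       per_level = per_level)
}
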