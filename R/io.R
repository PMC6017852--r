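# Plain-text interchange formats. All writers use vanilla CSV with a
# header; numbers are written with full (15 significant digit) precision
# so writer -> reader -> writer round-trips are bit-identical.

#' Chromatogram CSV I/O
#'
#' Two columns, `time_min,intensity`, header required. The companion
#' ground-truth writer emits `analyte,rt_min,area_true,conc_true` for
#' simulated traces.
#'
#' @param chrom A [chromatogram()].
#' @param path File path.
#' @return `write_*` returns `path` invisibly; `read_chromatogram_csv`
#'   returns a [chromatogram()].
#' @export
write_chromatogram_csv <- function(chrom, path) {
  utils::write.csv(data.frame(time_min = chrom$time,
                              intensity = chrom$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  d <- utils::read.csv(path)
  check_that(all(c("time_min", "intensity") %in% names(d)),
             "chromatogram CSV needs columns time_min,intensity")
  chromatogram(d$time_min, d$intensity, meta = list(source = path))
}

#' @rdname write_chromatogram_csv
#' @export
write_truth_csv <- function(chrom, path) {
  tr <- chrom$meta$truth
  check_that(!is.null(tr), "chromatogram carries no ground truth")
  utils::write.csv(tr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Peak-table CSV
#'
#' Columns `analyte,rt_min,rrt,area,rpa,height,snr,plates,tailing,
#' resolution`; absent metrics are written as empty fields.
#'
#' @param table A `peak_table`.
#' @param path File path.
#' @export
write_peak_table_csv <- function(table, path) {
  cols <- c("analyte", "rt_min", "rrt", "area", "rpa", "height", "snr",
            "plates", "tailing", "resolution")
  utils::write.csv(as.data.frame(table)[cols], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Content-matrix CSV I/O
#'
#' `sample,PQ-1,...,PQ-6` with concentrations in ug/mL.
#'
#' @param m A [batch_content_matrix].
#' @param path File path.
#' @param method Method tag applied on read.
#' @export
write_content_matrix_csv <- function(m, path) {
  d <- data.frame(sample = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_content_matrix_csv
#' @export
read_content_matrix_csv <- function(path, method = "ESM") {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[setdiff(names(d), "sample")])
  rownames(m) <- d$sample
  batch_content_matrix(m, method = method)
}

#' Calibration-set CSV
#'
#' `analyte,slope,intercept,r,range_low,range_high,lod,loq,n`.
#'
#' @param curves Named list of [calibration_curve()]s.
#' @param path File path.
#' @export
write_calibration_csv <- function(curves, path) {
  d <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(analyte = cv$analyte, slope = cv$slope,
               intercept = cv$intercept, r = cv$r,
               range_low = cv$range[1], range_high = cv$range[2],
               lod = cv$lod, loq = cv$loq, n = cv$n,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' RCF CSVs
#'
#' Long per-level table `analyte,level,f` and summary
#' `analyte,mean_f,rsd_pct`.
#'
#' @param rcfs Named list of [rcf_estimate()]s.
#' @param path,summary_path File paths (either may be `NULL` to skip).
#' @export
write_rcf_csv <- function(rcfs, path = NULL, summary_path = NULL) {
  if (!is.null(path)) {
    d <- do.call(rbind, lapply(rcfs, function(r) {
      data.frame(analyte = r$analyte, level = names(r$levels),
                 f = unname(r$levels), stringsAsFactors = FALSE)
    }))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path)) {
    s <- do.call(rbind, lapply(rcfs, function(r) {
      data.frame(analyte = r$analyte, mean_f = r$mean_f,
                 rsd_pct = r$rsd_pct, stringsAsFactors = FALSE)
    }))
    utils::write.csv(s, summary_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_rcf_csv
#' @export
read_rcf_summary_csv <- function(path) {
  d <- utils::read.csv(path)
  stats::setNames(d$mean_f, d$analyte)
}

#' Method-comparison CSV
#'
#' Per-cell table `sample,analyte,esm,qams,pair_sd` followed by the
#' per-analyte p-values in `analyte,p_two_tailed` (separate file).
#'
#' @param cmp A [compare_methods()] result.
#' @param esm,qams The matrices that were compared.
#' @param path,p_path File paths.
#' @export
write_comparison_csv <- function(cmp, esm, qams, path, p_path = NULL) {
  cells <- expand.grid(sample = rownames(esm), analyte = colnames(esm),
                       stringsAsFactors = FALSE)
  cells$esm <- esm[cbind(cells$sample, cells$analyte)]
  cells$qams <- qams[cbind(cells$sample, cells$analyte)]
  cells$pair_sd <- cmp$pair_sd[cbind(cells$sample, cells$analyte)]
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  if (!is.null(p_path)) {
    utils::write.csv(data.frame(analyte = names(cmp$p_value),
                                p_two_tailed = unname(cmp$p_value)),
                     p_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Export a Ward dendrogram as Newick text
#'
#' Branch lengths are merge-height differences (leaf branches run from
#' height zero), so the tree is ultrametric with tip-to-root distance
#' equal to the final merge height.
#'
#' @param result An [hca_ward()] result.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned instead.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_dendrogram_newick <- function(result, path = NULL) {
  h <- result$height
  node_str <- function(e, parent_h) {
    if (e < 0) {
      sprintf("%s:%.10g", gsub("[,:;()\\s]", "_", result$labels[-e], perl = TRUE),
              parent_h)
    } else {
      sprintf("(%s,%s):%.10g",
              node_str(result$merge[e, 1], h[e]),
              node_str(result$merge[e, 2], h[e]),
              parent_h - h[e])
    }
  }
  top <- length(h)
  nwk <- sprintf("(%s,%s);",
                 node_str(result$merge[top, 1], h[top]),
                 node_str(result$merge[top, 2], h[top]))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
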