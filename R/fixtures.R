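#' Load a packaged reference table
#'
#' The package ships the reference tables of the validated KMI method as
#' plain-text fixtures: the per-analyte calibration curves, the six-level
#' relative-correction-factor (RCF) determinations, the 3 instrument x 3
#' column RCF robustness grid, and the 20-batch ESM/QAMS content table.
#'
#' @param name One of `"calibration"`, `"rcf_levels"`, `"robustness"`,
#'   `"batch_contents"`.
#' @return A typed object at full printed precision:
#'   \describe{
#'     \item{calibration}{a list of [calibration_curve] objects, one per
#'       analyte, named by analyte.}
#'     \item{rcf_levels}{a data frame with column `level` (`C1`..`C6`) and
#'       one numeric column per analyte PQ-1..PQ-5.}
#'     \item{robustness}{a data frame with columns `instrument`, `column`
#'       and one numeric column per analyte PQ-1..PQ-5 (nine cells).}
#'     \item{batch_contents}{a list with elements `esm` and `qams`
#'       ([batch_content_matrix] objects, 20 samples x 6 analytes),
#'       `pair_sd` (20 x 5 matrix of printed ESM/QAMS pair SDs) and
#'       `total` (named vector, the printed per-batch totals). The QAMS
#'       matrix carries the ESM values in its PQ-6 column: the marker is
#'       by definition quantified on its own calibration curve.}
#'   }
#' @export
#' @examples
#' cal <- load_fixture("calibration")
#' cal[["PQ-6"]]$slope
load_fixture <- function(name) {
  available <- c("calibration", "rcf_levels", "robustness", "batch_contents")
  if (!is.character(name) || length(name) != 1L || !name %in% available) {
    stop("unknown fixture ", deparse(name), "; available: ",
         paste(available, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "qamskit",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  switch(name,
    calibration = {
      curves <- lapply(seq_len(nrow(raw)), function(i) {
        r <- raw[i, ]
        calibration_curve(analyte = r$analyte, slope = r$slope,
                          intercept = r$intercept, r = r$r,
                          range = c(r$range_low, r$range_high),
                          lod = r$lod, loq = r$loq, n = 6L)
      })
      stats::setNames(curves, raw$analyte)
    },
    rcf_levels = raw,
    robustness = raw,
    batch_contents = {
      samples <- raw$sample
      five <- c("PQ-1", "PQ-2", "PQ-3", "PQ-4", "PQ-5")
      esm <- cbind(
        as.matrix(raw[paste0(five, "_esm")]),
        `PQ-6` = raw[["PQ-6_esm"]]
      )
      qams <- cbind(
        as.matrix(raw[paste0(five, "_qams")]),
        `PQ-6` = raw[["PQ-6_esm"]]
      )
      colnames(esm) <- colnames(qams) <- c(five, "PQ-6")
      rownames(esm) <- rownames(qams) <- samples
      pair_sd <- as.matrix(raw[paste0(five, "_sd")])
      dimnames(pair_sd) <- list(samples, five)
      list(
        esm = batch_content_matrix(esm[, analytes()], method = "ESM"),
        qams = batch_content_matrix(qams[, analytes()], method = "QAMS"),
        pair_sd = pair_sd,
        total = stats::setNames(raw$total, samples)
      )
    }
  )
}

#' Samples x analytes content matrix
#'
#' A rectangular, fully observed, non-negative concentration table
#' (ug/mL) tagged with the quantitation method that produced it. This is
#' the exchange container between quantitation, method comparison and
#' chemometrics.
#'
#' @param values Numeric matrix (or coercible data frame), samples in
#'   rows, analytes in columns; dimnames required.
#' @param method Method tag, `"ESM"` or `"QAMS"`.
#' @return A `batch_content_matrix`: a numeric matrix with a `method`
#'   attribute.
#' @export
#' @examples
#' m <- matrix(1:4 + 0, 2, 2,
#'             dimnames = list(c("S1", "S2"), c("PQ-1", "PQ-6")))
#' batch_content_matrix(m, "ESM")
batch_content_matrix <- function(values, method = c("ESM", "QAMS")) {
  method <- match.arg(method)
  values <- as.matrix(values)
  check_that(is.numeric(values), "content matrix must be numeric")
  check_that(!is.null(rownames(values)) && !is.null(colnames(values)),
             "content matrix needs sample row names and analyte column names")
  check_that(!anyNA(values), "content matrix must have no missing cells")
  check_that(all(values >= 0), "content matrix values must be >= 0")
  structure(values, method = method, class = c("batch_content_matrix", class(values)))
}

#' @export
print.batch_content_matrix <- function(x, ...) {
  cat(sprintf("<batch_content_matrix> %d samples x %d analytes [%s]\n",
              nrow(x), ncol(x), attr(x, "method")))
  print(unclass(x), ...)
  invisible(x)
}
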