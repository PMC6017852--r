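#' Estimate the chromatographic baseline and noise level
#'
#' The baseline is a wide running median (window much wider than any
#' peak), which tracks slow drift while ignoring the narrow analyte
#' peaks. The noise SD is the robust SD (median absolute deviation x
#' 1.4826) of the baseline-subtracted signal, computed after discarding
#' points more than five robust SDs above the baseline so the peaks do
#' not inflate it.
#'
#' @param chrom A [chromatogram()].
#' @param window_min Smoothing window, minutes (default 2).
#' @return A `baseline_estimate`: list with `baseline` (numeric, one
#'   value per time point) and `noise_sd`.
#' @export
estimate_baseline <- function(chrom, window_min = 2) {
  check_that(inherits(chrom, "chromatogram"), "chrom must be a chromatogram")
  dt <- chrom$time[2] - chrom$time[1]
  k <- max(3L, as.integer(round(window_min / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  check_that(length(chrom$intensity) >= k,
             "trace (%d samples) shorter than the smoothing window (%d)",
             length(chrom$intensity), k)
  base <- as.numeric(stats::runmed(chrom$intensity, k, endrule = "median"))
  resid <- chrom$intensity - base
  s0 <- stats::mad(resid)
  keep <- if (s0 > 0) abs(resid) < 5 * s0 else rep(TRUE, length(resid))
  noise_sd <- stats::mad(resid[keep])
  structure(list(baseline = base, noise_sd = noise_sd),
            class = "baseline_estimate")
}

#' Detect candidate peak apexes
#'
#' Local maxima of the baseline-subtracted signal whose height is at
#' least `min_snr` noise SDs above the baseline; neighbouring maxima are
#' only reported as distinct peaks when separated by a genuine valley
#' (topographic prominence at least as large as the height threshold),
#' which keeps noise wiggles riding on one peak from splitting it.
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Minimum height / noise-SD ratio (> 0).
#' @param baseline Optional precomputed [estimate_baseline()] result.
#' @return Data frame of apexes ordered by time: `index`, `time`,
#'   `height` (baseline-subtracted).
#' @export
detect_peaks <- function(chrom, min_snr = 10, baseline = NULL) {
  check_that(min_snr > 0, "min_snr must be > 0")
  if (is.null(baseline)) baseline <- estimate_baseline(chrom)
  r <- chrom$intensity - baseline$baseline
  n <- length(r)
  thr <- max(min_snr * baseline$noise_sd, 1e-9 * max(abs(r), 1e-300))
  i <- 2:(n - 1)
  cand <- i[r[i] >= r[i - 1] & r[i] > r[i + 1] & r[i] >= thr & r[i] > 0]
  if (!length(cand)) {
    return(data.frame(index = integer(), time = numeric(), height = numeric()))
  }
  # prominence screen, processed tallest-first
  ord <- cand[order(-r[cand])]
  accepted <- integer()
  for (p in ord) {
    prom <- prominence_at(r, p, accepted)
    if (prom >= thr) accepted <- c(accepted, p)
  }
  accepted <- sort(accepted)
  data.frame(index = accepted, time = chrom$time[accepted],
             height = r[accepted])
}

# prominence of candidate apex p relative to already-accepted (taller or
# equal) apexes: drop to the deepest valley separating p from its nearest
# accepted neighbour on each side; no neighbour => full height.
prominence_at <- function(r, p, accepted) {
  h <- r[p]
  key <- function(side_idx) {
    if (!length(side_idx)) return(0)          # no higher neighbour this side
    q <- side_idx[which.min(abs(side_idx - p))]
    min(r[min(p, q):max(p, q)])
  }
  left <- accepted[accepted < p]
  right <- accepted[accepted > p]
  h - max(key(left), key(right))
}

#' Integrate a detected peak
#'
#' Bounds run from the apex outward to the nearest valley (signal starts
#' rising again) or to baseline return, defined as the signal falling
#' below 0.5% of the apex height; the area is the trapezoidal integral of
#' the baseline-subtracted signal between the bounds, and the half-height
#' width is measured by linear interpolation at 50% of the apex height.
#'
#' @param chrom A [chromatogram()].
#' @param apex Apex index (from [detect_peaks()]) or a one-row slice of
#'   its output.
#' @param baseline Optional precomputed [estimate_baseline()] result.
#' @return A `peak`: list with `t_r`, `height`, `area`, `width_half`,
#'   `start`, `end` (minutes, conceptually the half-open window
#'   `[start, end)`), `snr`, and placeholders for `plates`, `tailing`,
#'   `resolution` filled by the metric functions.
#' @export
integrate_peak <- function(chrom, apex, baseline = NULL) {
  if (is.data.frame(apex)) apex <- apex$index[1]
  apex <- as.integer(apex)
  if (is.null(baseline)) baseline <- estimate_baseline(chrom)
  r <- chrom$intensity - baseline$baseline
  n <- length(r)
  check_that(apex >= 2L && apex <= n - 1L, "apex index out of range")
  h <- r[apex]
  check_that(h > 0, "apex height must be positive")
  floor_lvl <- 0.005 * h
  walk <- function(step) {
    j <- apex
    repeat {
      nxt <- j + step
      if (nxt < 1L || nxt > n) {
        if (r[j] > floor_lvl) {
          stop("peak clipped at run boundary (signal above baseline-return ",
               "level at the trace edge)", call. = FALSE)
        }
        return(j)
      }
      if (r[nxt] > r[j]) return(j)           # valley: signal rises again
      j <- nxt
      if (r[j] <= floor_lvl) return(j)       # baseline return
    }
  }
  i0 <- walk(-1L)
  i1 <- walk(+1L)
  check_that(i1 > i0 + 1L, "zero-width peak at index %d", apex)
  seg <- i0:i1
  area <- sum(diff(chrom$time[seg]) * (r[seg][-1] + r[seg][-length(seg)]) / 2)
  check_that(area > 0, "non-positive integrated area at index %d", apex)
  half <- h / 2
  tl <- cross_time(chrom$time, pmax(r, 0), half, apex, "left")
  tr_ <- cross_time(chrom$time, pmax(r, 0), half, apex, "right")
  check_that(is.finite(tl) && is.finite(tr_) && tr_ > tl,
             "cannot measure half-height width at index %d", apex)
  structure(
    list(t_r = chrom$time[apex], height = h, area = area,
         width_half = tr_ - tl, start = chrom$time[i0], end = chrom$time[i1],
         snr = if (baseline$noise_sd > 0) h / baseline$noise_sd else Inf,
         plates = NA_real_, tailing = NA_real_, resolution = NA_real_),
    class = "peak"
  )
}

#' Theoretical plate number
#'
#' Column-efficiency estimate from the half-height width (European
#' Pharmacopoeia constant): `N = 5.54 (t_R / w_half)^2`.
#'
#' @param peak A `peak` from [integrate_peak()].
#' @return Plate number (dimensionless).
#' @export
#' @examples
#' plates(structure(list(t_r = 15.75, width_half = 0.09), class = "peak"))
plates <- function(peak) {
  check_that(peak$width_half > 0, "half-height width must be > 0")
  5.54 * (peak$t_r / peak$width_half)^2
}

#' USP tailing factor
#'
#' `T = W_0.05 / (2 f)` where `W_0.05` is the full peak width at 5% of
#' the apex height and `f` the front half-width at the same level, both
#' measured on the baseline-subtracted signal inside the integration
#' bounds. Returns `NA` when the 5% level is not reached inside the
#' bounds (metric absent, not an error).
#'
#' @param peak A `peak` from [integrate_peak()].
#' @param chrom The chromatogram the peak came from.
#' @param baseline Optional precomputed [estimate_baseline()] result.
#' @return Tailing factor, or `NA_real_`.
#' @export
tailing_factor <- function(peak, chrom, baseline = NULL) {
  if (is.null(baseline)) baseline <- estimate_baseline(chrom)
  r <- chrom$intensity - baseline$baseline
  inside <- chrom$time >= peak$start & chrom$time <= peak$end
  tt <- chrom$time[inside]
  y <- r[inside]
  i <- which.max(y)
  lvl <- 0.05 * y[i]
  tl <- cross_time(tt, y, lvl, i, "left")
  tr_ <- cross_time(tt, y, lvl, i, "right")
  if (!is.finite(tl) || !is.finite(tr_)) return(NA_real_)
  (tr_ - tl) / (2 * (tt[i] - tl))
}

#' Resolution between two peaks
#'
#' `R_s = 2 (t_R2 - t_R1) / (W_1 + W_2)` with base widths approximated
#' from the half-height widths as `W = 1.699 w_half` (Gaussian identity).
#'
#' @param prev,next_ Two `peak`s with `prev$t_r <= next_$t_r`.
#' @return Resolution (0 for identical apex times).
#' @export
resolution <- function(prev, next_) {
  check_that(prev$t_r <= next_$t_r, "peaks must be given in elution order")
  if (next_$t_r == prev$t_r) return(0)
  2 * (next_$t_r - prev$t_r) /
    (1.699 * (prev$width_half + next_$width_half))
}

#' Relative-retention-time library
#'
#' Expected RRT (vs the PQ-6 reference peak) and matching tolerance per
#' analyte. The defaults are the typical values of the reference system
#' (mean +/- SD): PQ-1 0.45 +/- 0.02, PQ-5 0.72 +/- 0.02, PQ-4
#' 0.75 +/- 0.02, PQ-3 0.83 +/- 0.01, PQ-2 1.18 +/- 0.01; the matching
#' window is the SD times `multiplier` (default 2, i.e. roughly a 95%
#' window under normal scatter).
#'
#' @param expected Named numeric of expected RRTs (must include PQ-6 = 1).
#' @param sd Named numeric of reported RRT SDs.
#' @param multiplier Window half-width in SD units.
#' @return An `rrt_library` data frame: `analyte`, `expected`, `tol`.
#' @export
#' @examples
#' default_rrt_library()
rrt_library <- function(expected, sd, multiplier = 2) {
  check_that(identical(sort(names(expected)), sort(names(sd))),
             "expected and sd must share analyte names")
  check_that(all(sd > 0) && multiplier > 0, "tolerances must be > 0")
  check_that(!anyDuplicated(names(expected)), "entries must be unique per analyte")
  ord <- order(expected)
  structure(
    data.frame(analyte = names(expected)[ord],
               expected = unname(expected)[ord],
               tol = unname(sd * multiplier)[ord],
               stringsAsFactors = FALSE),
    class = c("rrt_library", "data.frame")
  )
}

#' @rdname rrt_library
#' @export
default_rrt_library <- function(multiplier = 2) {
  rrt_library(
    expected = c("PQ-1" = 0.45, "PQ-5" = 0.72, "PQ-4" = 0.75,
                 "PQ-3" = 0.83, "PQ-6" = 1.00, "PQ-2" = 1.18),
    sd = c("PQ-1" = 0.02, "PQ-5" = 0.02, "PQ-4" = 0.02,
           "PQ-3" = 0.01, "PQ-6" = 0.01, "PQ-2" = 0.01),
    multiplier = multiplier
  )
}

# Greedy one-to-one matching of peaks (by their RRTs) to library
# windows, the reference slot being fixed to ref_idx. Smallest
# |RRT - expected| wins; ties (quantized to 1e-9 to absorb fp jitter) go
# to the smaller expected RRT, then to the earlier peak. Returns the
# per-peak analyte assignment (NA = unassigned).
match_rrt_windows <- function(rrt, library, ref_idx) {
  assignment <- rep(NA_character_, length(rrt))
  assignment[ref_idx] <- REFERENCE_ANALYTE
  cand <- do.call(rbind, lapply(seq_len(nrow(library)), function(j) {
    d <- abs(rrt - library$expected[j])
    hit <- which(d <= library$tol[j])
    if (!length(hit)) return(NULL)
    data.frame(peak = hit, analyte = library$analyte[j],
               expected = library$expected[j], dist = d[hit])
  }))
  if (!is.null(cand)) {
    cand <- cand[cand$peak != ref_idx & cand$analyte != REFERENCE_ANALYTE, ]
    cand <- cand[order(round(cand$dist, 9), cand$expected, cand$peak), ]
    used <- REFERENCE_ANALYTE
    for (k in seq_len(nrow(cand))) {
      p <- cand$peak[k]; a <- cand$analyte[k]
      if (!is.na(assignment[p]) || a %in% used) next
      assignment[p] <- a
      used <- c(used, a)
    }
  }
  assignment
}

#' Assign analytes to peaks by relative retention time
#'
#' The PQ-6 reference peak is fixed first: unless `reference_time` is
#' given, every peak is tried as a provisional reference and the one
#' whose induced RRTs place the most peaks inside library windows wins
#' (largest area breaks ties) -- in routine use the analyst knows the
#' abundant PQ-6 peak, which is what this emulates. Every other peak is
#' then assigned to the analyte whose expected-RRT window contains its
#' RRT; competing (peak, analyte) matches are resolved by smallest
#' `|RRT - expected|`, an exact tie going to the smaller expected RRT
#' (so a peak exactly between the PQ-5 and PQ-4 windows is called PQ-5),
#' then to the earlier-eluting peak. Each analyte is assigned at most one
#' peak and vice versa.
#'
#' @param peaks List of `peak` objects (from [integrate_peak()]).
#' @param library An [rrt_library()].
#' @param reference_time Optional explicit PQ-6 apex time (minutes);
#'   the nearest peak becomes the reference.
#' @return A `peak_table` data frame with one row per peak: `analyte`
#'   (`NA` when unassigned), `rt_min`, `rrt`, `area`, `rpa`, `height`,
#'   `snr`, `width_half`, `plates`, `tailing`, `resolution` (vs the
#'   preceding assigned peak). The reference row has `rrt = 1` and
#'   `rpa = 1` exactly.
#' @export
assign_analytes <- function(peaks, library = default_rrt_library(),
                            reference_time = NULL) {
  check_that(inherits(library, "rrt_library"), "library must be an rrt_library")
  if (!length(peaks)) stop("reference peak not found (no peaks)", call. = FALSE)
  times <- vapply(peaks, function(p) p$t_r, numeric(1))
  areas <- vapply(peaks, function(p) p$area, numeric(1))
  ord <- order(times)
  peaks <- peaks[ord]; times <- times[ord]; areas <- areas[ord]

  if (!is.null(reference_time)) {
    ref_idx <- which.min(abs(times - reference_time))
  } else {
    # provisional referencing: try every peak as PQ-6 and keep the one
    # whose induced RRTs admit the largest one-to-one window matching;
    # area breaks ties (PQ-6 is among the most abundant peaks)
    score <- vapply(seq_along(peaks), function(i) {
      sum(!is.na(match_rrt_windows(times / times[i], library, i)))
    }, numeric(1))
    best <- which(score == max(score))
    ref_idx <- best[which.max(areas[best])]
    if (max(score) < 1) stop("reference peak not found", call. = FALSE)
  }
  rrt <- times / times[ref_idx]
  assignment <- match_rrt_windows(rrt, library, ref_idx)
  rpa <- areas / areas[ref_idx]
  rrt[ref_idx] <- 1; rpa[ref_idx] <- 1  # exact by construction
  tab <- data.frame(
    analyte = assignment,
    rt_min = times,
    rrt = rrt,
    area = areas,
    rpa = rpa,
    height = vapply(peaks, function(p) p$height, numeric(1)),
    snr = vapply(peaks, function(p) p$snr, numeric(1)),
    width_half = vapply(peaks, function(p) p$width_half, numeric(1)),
    plates = vapply(peaks, plates, numeric(1)),
    tailing = vapply(peaks, function(p) p$tailing, numeric(1)),
    resolution = NA_real_,
    stringsAsFactors = FALSE
  )
  assigned <- which(!is.na(tab$analyte))
  if (length(assigned) > 1) {
    for (k in 2:length(assigned)) {
      tab$resolution[assigned[k]] <-
        resolution(peaks[[assigned[k - 1]]], peaks[[assigned[k]]])
    }
  }
  structure(tab, class = c("peak_table", "data.frame"),
            reference = REFERENCE_ANALYTE)
}

#' Chromatogram to analyte-assigned peak table
#'
#' Convenience pipeline: baseline estimation, apex detection, integration,
#' suitability metrics, and RRT-based assignment in one call.
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Detection threshold passed to [detect_peaks()].
#' @param library An [rrt_library()].
#' @param reference_time Optional explicit reference apex time.
#' @return A `peak_table` (see [assign_analytes()]).
#' @export
process_chromatogram <- function(chrom, min_snr = 10,
                                 library = default_rrt_library(),
                                 reference_time = NULL) {
  bl <- estimate_baseline(chrom)
  apexes <- detect_peaks(chrom, min_snr = min_snr, baseline = bl)
  if (!nrow(apexes)) stop("reference peak not found (no peaks)", call. = FALSE)
  peaks <- lapply(apexes$index, function(i) {
    p <- integrate_peak(chrom, i, baseline = bl)
    p$tailing <- tailing_factor(p, chrom, baseline = bl)
    p
  })
  assign_analytes(peaks, library = library, reference_time = reference_time)
}
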