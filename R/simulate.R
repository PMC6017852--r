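#' Linear detector response model
#'
#' Per-analyte linear peak-area response `area = slope * conc + intercept`
#' (area in detector units x minutes, concentration in ug/mL). This is
#' both the simulator's forward model and the external-standard (ESM)
#' calibration shipped with the package.
#'
#' @param slope Named numeric, area units per ug/mL, one entry per
#'   analyte; all > 0.
#' @param intercept Named numeric, same names as `slope`.
#' @return A `response_model` data frame with columns `analyte`, `slope`,
#'   `intercept`.
#' @export
#' @examples
#' default_response_model()
response_model <- function(slope, intercept) {
  check_that(is.numeric(slope) && is.numeric(intercept),
             "slope and intercept must be numeric")
  check_that(!is.null(names(slope)) && identical(names(slope), names(intercept)),
             "slope and intercept must share analyte names")
  check_that(all(slope > 0), "every slope must be > 0")
  structure(
    data.frame(analyte = names(slope), slope = unname(slope),
               intercept = unname(intercept), stringsAsFactors = FALSE),
    class = c("response_model", "data.frame")
  )
}

#' @rdname response_model
#' @param zero_intercept If `TRUE`, drop the intercepts (useful for the
#'   exactness limits of QAMS: with `b = 0` the relative correction
#'   factors are concentration-independent).
#' @export
default_response_model <- function(zero_intercept = FALSE) {
  cal <- load_fixture("calibration")
  slope <- vapply(cal, function(c) c$slope, numeric(1))
  intercept <- if (zero_intercept) {
    stats::setNames(rep(0, length(cal)), names(cal))
  } else {
    vapply(cal, function(c) c$intercept, numeric(1))
  }
  response_model(slope, intercept)
}

response_for <- function(response, analyte) {
  i <- match(analyte, response$analyte)
  check_that(!anyNA(i), "analyte %s not in response model",
             paste(analyte[is.na(i)], collapse = ", "))
  response[i, , drop = FALSE]
}

#' Simulated instrument profile
#'
#' Describes the chromatographic system that the simulator emulates: a
#' 55-min gradient run sampled uniformly, six peaks placed by relative
#' retention time (RRT) against the PQ-6 reference peak, near-Gaussian
#' peak shapes with a configurable USP tailing-factor target, white
#' baseline noise and optional linear drift.
#'
#' The absolute reference retention time is a free parameter of the
#' simulated instrument (only RRTs matter downstream); the default puts
#' the PQ-6 apex at 35 min, inside the gradient window. The default
#' noise SD (1 detector unit) keeps the signal-to-noise ratio of every
#' analyte above 1000 at mid-range concentrations, matching the
#' suitability envelope of the reference system.
#'
#' @param reference_rt Apex time of the PQ-6 reference peak, minutes.
#' @param rrt Named numeric of expected RRTs (dimensionless); must
#'   include every analyte and have `rrt["PQ-6"] == 1` exactly.
#' @param width_half Peak width at half height, minutes; scalar or named
#'   per analyte.
#' @param tailing USP tailing-factor target: 1 gives a symmetric
#'   Gaussian, values above 1 a tailing peak, values below 1 fronting.
#' @param noise_sd Baseline white-noise SD, detector units per sample.
#' @param drift Linear baseline drift slope, detector units per minute.
#' @param dt Sampling interval, minutes.
#' @param run_length Run length, minutes.
#' @return An `instrument_profile` list.
#' @export
#' @examples
#' instrument_profile(noise_sd = 0)
instrument_profile <- function(reference_rt = 35,
                               rrt = c("PQ-1" = 0.45, "PQ-5" = 0.72,
                                       "PQ-4" = 0.75, "PQ-3" = 0.83,
                                       "PQ-6" = 1.00, "PQ-2" = 1.18),
                               width_half = 0.12,
                               tailing = 1.0,
                               noise_sd = 1.0,
                               drift = 0,
                               dt = 0.01,
                               run_length = 55) {
  check_that(all(analytes() %in% names(rrt)), "rrt must cover all analytes")
  rrt <- rrt[analytes()]
  check_that(rrt[[REFERENCE_ANALYTE]] == 1,
             "RRT of %s must be exactly 1", REFERENCE_ANALYTE)
  check_that(all(rrt > 0) && all(rrt < run_length / reference_rt),
             "all RRTs must lie in (0, run_length / reference_rt)")
  if (length(width_half) == 1L && is.null(names(width_half))) {
    width_half <- stats::setNames(rep(width_half, 6), analytes())
  }
  width_half <- width_half[analytes()]
  check_that(all(width_half > 0), "peak widths must be > 0")
  check_that(dt > 0 && run_length > 0, "dt and run_length must be > 0")
  check_that(tailing > 0, "tailing target must be > 0")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(
    list(reference_rt = reference_rt, rrt = rrt, width_half = width_half,
         tailing = tailing, noise_sd = noise_sd, drift = drift, dt = dt,
         run_length = run_length),
    class = "instrument_profile"
  )
}

#' Injection specification
#'
#' True (ground-truth) concentrations behind a simulated injection.
#'
#' @param conc Named numeric of true concentrations (ug/mL); missing
#'   analytes are taken as 0; all >= 0.
#' @param label `"sample"`, `"standard"` or `"blank"` (a blank must have
#'   all-zero concentrations; it emulates the negative preparation).
#' @param replicate Replicate index.
#' @param seed Integer RNG seed used for this injection's noise; may be
#'   `NULL` only for noiseless simulation.
#' @param level Optional level id (e.g. `"C3"`) for standards.
#' @return An `injection_spec` list.
#' @export
#' @examples
#' injection_spec(c("PQ-6" = 50), label = "standard", seed = 1)
injection_spec <- function(conc = numeric(), label = "sample",
                           replicate = 1L, seed = NULL, level = NA_character_) {
  check_that(label %in% c("sample", "standard", "blank"),
             "label must be sample, standard or blank")
  full <- stats::setNames(rep(0, 6), analytes())
  if (length(conc)) {
    check_that(!is.null(names(conc)) && all(names(conc) %in% analytes()),
               "conc must be named by analyte")
    check_that(all(conc >= 0), "concentrations must be >= 0")
    full[names(conc)] <- conc
  }
  if (label == "blank") {
    check_that(all(full == 0), "a blank must have all-zero concentrations")
  }
  structure(list(conc = full, label = label, replicate = as.integer(replicate),
                 seed = seed, level = level),
            class = "injection_spec")
}

#' Uniformly sampled chromatogram
#'
#' @param time Strictly increasing time grid with constant step, minutes.
#' @param intensity Finite detector signal, same length as `time`.
#' @param meta List of acquisition metadata (spec, profile, ground truth).
#' @return A `chromatogram` list.
#' @export
chromatogram <- function(time, intensity, meta = list()) {
  check_that(length(time) == length(intensity) && length(time) >= 2L,
             "time and intensity must have equal length >= 2")
  dsteps <- diff(time)
  check_that(all(dsteps > 0), "time must be strictly increasing")
  check_that(diff(range(dsteps)) <= 1e-9 * max(dsteps),
             "time grid must have constant step")
  check_that(all(is.finite(intensity)), "intensity must be finite")
  structure(list(time = time, intensity = intensity, meta = meta),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d samples, %.4g-%.4g min, dt = %.4g min\n",
              length(x$time), min(x$time), max(x$time), x$time[2] - x$time[1]))
  invisible(x)
}

# ---- peak shape -----------------------------------------------------------
# Exponentially modified Gaussian, unit area. Evaluated in log space so
# small tau does not overflow exp(sigma^2 / (2 tau^2)).
emg_density <- function(t, mu, sigma, tau) {
  if (tau < 1e-4 * sigma) {
    return(stats::dnorm(t, mu, sigma))
  }
  z <- (sigma / tau - (t - mu) / sigma) / sqrt(2)
  # log(erfc(z)) = log(2) + pnorm(-z * sqrt(2), log.p = TRUE)
  log_h <- -log(2 * tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    log(2) + stats::pnorm(-z * sqrt(2), log.p = TRUE)
  exp(log_h)
}

# USP tailing factor of a shape sampled on grid tt (front half-width f and
# full width W at 5% of apex height): T = W / (2 f).
shape_tailing <- function(tt, y) {
  i <- which.max(y)
  lvl <- 0.05 * y[i]
  tl <- cross_time(tt, y, lvl, i, side = "left")
  tr <- cross_time(tt, y, lvl, i, side = "right")
  (tr - tl) / (2 * (tt[i] - tl))
}

# linear-interpolated crossing of level `lvl` walking away from apex i
cross_time <- function(tt, y, lvl, i, side = c("left", "right")) {
  side <- match.arg(side)
  idx <- if (side == "left") rev(seq_len(i)) else i:length(y)
  below <- which(y[idx] < lvl)
  if (!length(below)) return(NA_real_)
  j2 <- idx[below[1]]                      # first sample below level
  j1 <- if (side == "left") j2 + 1L else j2 - 1L  # last sample above
  tt[j1] + (tt[j2] - tt[j1]) * (y[j1] - lvl) / (y[j1] - y[j2])
}

# Solve for the EMG tau giving a USP tailing target; target < 1 is
# produced by time-mirroring the shape for tau solving 1/target geometry.
emg_tau_for_tailing <- function(sigma, target) {
  if (abs(target - 1) < 1e-6) return(list(tau = 0, mirror = FALSE))
  mirror <- target < 1
  # a time-mirrored EMG reaches fronting factors down to 1/2
  check_that(!mirror || target > 0.5,
             "fronting targets below 0.5 are out of reach for this shape")
  metric <- function(tau) {
    tt <- seq(-8 * sigma - 10 * tau, 8 * sigma + 10 * tau, by = sigma / 50)
    y <- emg_density(tt, 0, sigma, tau)
    if (mirror) shape_tailing(tt, rev(y)) else shape_tailing(tt, y)
  }
  f <- function(tau) metric(tau) - target
  lo <- 1e-3 * sigma
  hi <- sigma
  while (f(lo) * f(hi) > 0 && hi < 100 * sigma) hi <- hi * 2
  check_that(f(lo) * f(hi) <= 0,
             "tailing target %.3g out of reachable range", target)
  tau <- stats::uniroot(f, c(lo, hi), tol = 1e-4 * sigma)$root
  list(tau = tau, mirror = mirror)
}

# Unit-area peak shape centred (apex) at `center` on grid tt.
peak_shape <- function(tt, center, width_half, tailing) {
  sigma <- width_half / (2 * sqrt(2 * log(2)))   # 2.3548 sigma = w1/2
  par <- emg_tau_for_tailing(sigma, tailing)
  if (par$tau == 0) {
    return(stats::dnorm(tt, center, sigma))
  }
  # locate the EMG apex offset, then shift so the apex lands on `center`
  gg <- seq(-6 * sigma, 6 * sigma + 6 * par$tau, by = sigma / 100)
  off <- gg[which.max(emg_density(gg, 0, sigma, par$tau))]
  if (par$mirror) {
    emg_density(-(tt - center) + off, 0, sigma, par$tau)
  } else {
    emg_density((tt - center) + off, 0, sigma, par$tau)
  }
}

# ---- operations -----------------------------------------------------------

#' Simulate one HPLC-UV injection
#'
#' Generates a chromatogram in which every analyte with a positive true
#' concentration contributes one peak centred at `RRT x reference_rt`
#' whose (noise-free) integrated area equals `max(0, slope * conc +
#' intercept)` under the response model; areas that the linear model
#' would make negative at very low concentration are clipped to zero
#' (a detector cannot integrate negative area). White Gaussian noise
#' with the profile's SD and optional linear drift are then added.
#'
#' @param spec An [injection_spec()].
#' @param response A [response_model()].
#' @param profile An [instrument_profile()].
#' @return A [chromatogram()] whose `meta` carries the spec, profile and
#'   a ground-truth table (`analyte`, `rt_min`, `area_true`, `conc_true`).
#' @export
#' @examples
#' p <- instrument_profile(noise_sd = 0)
#' ch <- simulate_injection(injection_spec(c("PQ-6" = 50)),
#'                          default_response_model(), p)
simulate_injection <- function(spec, response = default_response_model(),
                               profile = instrument_profile()) {
  check_that(inherits(spec, "injection_spec"), "spec must be an injection_spec")
  check_that(inherits(profile, "instrument_profile"),
             "profile must be an instrument_profile")
  check_that(all(spec$conc >= 0), "negative concentration rejected")
  if (profile$noise_sd > 0) {
    check_that(!is.null(spec$seed),
               "a seed is required when simulating with noise (noise_sd > 0)")
  }
  tt <- seq(0, profile$run_length, by = profile$dt)
  y <- profile$drift * tt
  truth <- data.frame(analyte = character(), rt_min = numeric(),
                      area_true = numeric(), conc_true = numeric(),
                      stringsAsFactors = FALSE)
  active <- names(spec$conc)[spec$conc > 0]
  for (a in active) {
    rt <- profile$rrt[[a]] * profile$reference_rt
    check_that(rt < profile$run_length,
               "peak center for %s (%.2f min) beyond run length (%.2f min)",
               a, rt, profile$run_length)
    r <- response_for(response, a)
    area <- max(0, r$slope * spec$conc[[a]] + r$intercept)
    if (area > 0) {
      y <- y + area * peak_shape(tt, rt, profile$width_half[[a]], profile$tailing)
    }
    truth <- rbind(truth, data.frame(
      analyte = a, rt_min = rt, area_true = area,
      conc_true = spec$conc[[a]], stringsAsFactors = FALSE))
  }
  if (profile$noise_sd > 0) {
    y <- y + with_seed(spec$seed,
                       stats::rnorm(length(tt), sd = profile$noise_sd))
  }
  chromatogram(tt, y, meta = list(spec = spec, profile = profile, truth = truth))
}

#' Mixed-standard dilution series
#'
#' Builds the specs of an `n_levels`-point mixed-standard series spanning
#' the working-solution concentration range of every analyte
#' (PQ-1 11.0-41.3, PQ-2 1.95-9.75, PQ-3 20.6-62.0, PQ-4 5.22-31.3,
#' PQ-5 2.00-14.1, PQ-6 2.00-100 ug/mL), evenly spaced per analyte, with
#' level ids `C1..Cn`. Level concentrations are simulator parameters (the
#' reference method prints only the ranges); evenly spaced levels are the
#' conventional design.
#'
#' @param response A [response_model()] (used for analyte validation).
#' @param n_levels Number of levels, >= 2; default 6 mirrors C1-C6.
#' @param seed Optional base seed; level `i` receives `seed + i`.
#' @return List of [injection_spec()]s named `C1..Cn`.
#' @export
#' @examples
#' length(make_standard_series(n_levels = 6))
make_standard_series <- function(response = default_response_model(),
                                 n_levels = 6, seed = NULL) {
  check_that(n_levels >= 2, "n_levels must be >= 2")
  response_for(response, rownames(STANDARD_RANGES))  # analytes must exist
  lev <- lapply(seq_len(n_levels), function(i) {
    conc <- STANDARD_RANGES[, "low"] +
      (i - 1) * (STANDARD_RANGES[, "high"] - STANDARD_RANGES[, "low"]) /
        (n_levels - 1)
    injection_spec(conc, label = "standard",
                   seed = if (is.null(seed)) NULL else seed + i,
                   level = paste0("C", i))
  })
  stats::setNames(lev, paste0("C", seq_len(n_levels)))
}

#' Simulate a batch sample set
#'
#' One injection per sample x replicate with true contents taken from a
#' [batch_content_matrix] (default: the packaged 20-batch ESM contents).
#'
#' @param truth A [batch_content_matrix] holding the true contents; must
#'   contain all six analytes.
#' @param replicates Replicates per sample (0 gives an empty list).
#' @param seed Base integer seed; injection seeds are derived
#'   deterministically from it.
#' @param response,profile Forward model passed to [simulate_injection()].
#' @return List of `list(spec =, chromatogram =)` pairs, named
#'   `<sample>_r<replicate>`.
#' @export
make_batch_dataset <- function(truth = load_fixture("batch_contents")$esm,
                               replicates = 1, seed = 1,
                               response = default_response_model(),
                               profile = instrument_profile()) {
  check_that(nrow(truth) >= 1, "truth needs at least one sample")
  missing <- setdiff(analytes(), colnames(truth))
  check_that(!length(missing), "truth is missing analyte column(s): %s",
             paste(missing, collapse = ", "))
  out <- list()
  if (replicates < 1) return(out)
  for (si in seq_len(nrow(truth))) {
    for (ri in seq_len(replicates)) {
      spec <- injection_spec(truth[si, analytes()], label = "sample",
                             replicate = ri,
                             seed = seed + 997L * si + ri)
      key <- sprintf("%s_r%d", rownames(truth)[si], ri)
      out[[key]] <- list(spec = spec,
                         chromatogram = simulate_injection(spec, response, profile))
    }
  }
  out
}
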