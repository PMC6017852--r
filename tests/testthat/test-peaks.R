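test_that("baseline estimation handles flat, noisy and drifting traces", {
  tt <- seq(0, 10, 0.01)
  flat <- chromatogram(tt, rep(0, length(tt)))
  bl <- estimate_baseline(flat)
  expect_equal(bl$baseline, rep(0, length(tt)))
  expect_equal(bl$noise_sd, 0)

  set.seed(5)
  noisy <- chromatogram(tt, 5 + rnorm(length(tt), sd = 0.1))
  bl2 <- estimate_baseline(noisy)
  expect_gt(mean(bl2$baseline), 4.9)
  expect_lt(mean(bl2$baseline), 5.1)
  expect_lt(abs(bl2$noise_sd - 0.1) / 0.1, 0.3)

  drifty <- chromatogram(tt, 3 * tt)
  bl3 <- estimate_baseline(drifty)
  slope <- coef(lm(bl3$baseline ~ tt))[2]
  expect_lt(abs(slope - 3) / 3, 0.1)

  expect_error(estimate_baseline(chromatogram(seq(0, 0.1, 0.01),
                                              rep(0, 11))),
               "shorter than the smoothing window")
})

test_that("peak detection finds resolved apexes and rejects bad thresholds", {
  expect_error(detect_peaks(gaussian_trace(), min_snr = 0), "min_snr")

  ch <- simulate_injection(make_standard_series()$C4,
                           profile = noiseless_profile())
  expect_equal(nrow(detect_peaks(ch, min_snr = 10)), 6)

  # two Gaussians 0.2 min apart: valley present, both reported
  tt <- seq(0, 4, 0.01)
  two <- chromatogram(tt, 1000 * dnorm(tt, 2.0, 0.05) +
                          800 * dnorm(tt, 2.2, 0.05))
  apexes <- detect_peaks(two, min_snr = 10)
  expect_equal(nrow(apexes), 2)
  expect_equal(apexes$time, c(2.0, 2.2), tolerance = 0.02)
})

test_that("integration recovers area and half-height width of a Gaussian", {
  ch <- gaussian_trace(center = 2, sigma = 0.05, area = 1000)
  pk <- integrate_peak(ch, which.max(ch$intensity))
  expect_equal(pk$area, 1000, tolerance = 0.005)
  expect_equal(pk$width_half, 2 * sqrt(2 * log(2)) * 0.05, tolerance = 0.02)
  expect_true(pk$start < pk$t_r && pk$t_r < pk$end)

  clipped <- gaussian_trace(center = 3.95, sigma = 0.05, t_max = 4)
  # explicit zero baseline: the running-median baseline would swallow the
  # edge peak on so short a trace, which is not what this contract probes
  bl0 <- structure(list(baseline = rep(0, length(clipped$time)),
                        noise_sd = 0), class = "baseline_estimate")
  expect_error(integrate_peak(clipped, which.max(clipped$intensity),
                              baseline = bl0),
               "clipped")
})

test_that("integration is additive for well-resolved neighbours", {
  tt <- seq(0, 6, 0.01)
  a <- 1000 * dnorm(tt, 2, 0.05)
  b <- 700 * dnorm(tt, 3, 0.05)
  both <- chromatogram(tt, a + b)
  pks <- detect_peaks(both, min_snr = 10)
  areas <- vapply(pks$index, function(i) integrate_peak(both, i)$area,
                  numeric(1))
  a1 <- integrate_peak(chromatogram(tt, a), which.max(a))$area
  b1 <- integrate_peak(chromatogram(tt, b), which.max(b))$area
  expect_equal(sum(areas), a1 + b1, tolerance = 0.005)
})

test_that("plate number follows the half-height formula", {
  expect_equal(plates(bare_peak(15.75, 0.09)), 5.54 * (15.75 / 0.09)^2)
  expect_equal(plates(bare_peak(15.75, 0.09)), 169662, tolerance = 1e-4)
  # defaults land inside the reference suitability range 30711-744241
  ch <- simulate_injection(make_standard_series()$C4,
                           profile = noiseless_profile())
  tab <- process_chromatogram(ch)
  expect_true(all(tab$plates > 30711 & tab$plates < 744241))
  expect_error(plates(bare_peak(10, 0)), "width")
})

test_that("tailing factor distinguishes symmetric, tailing and fronting peaks", {
  ch <- gaussian_trace()
  bl <- estimate_baseline(ch)
  pk <- integrate_peak(ch, which.max(ch$intensity), baseline = bl)
  expect_equal(tailing_factor(pk, ch, baseline = bl), 1, tolerance = 0.02)

  sim_tail <- function(target) {
    prof <- noiseless_profile(tailing = target)
    ch <- simulate_injection(injection_spec(c("PQ-6" = 50)), profile = prof)
    tab <- process_chromatogram(ch)
    tab$tailing[tab$analyte == "PQ-6"]
  }
  expect_equal(sim_tail(1.3), 1.3, tolerance = 0.05)
  expect_gt(sim_tail(1.3), 1)
  expect_equal(sim_tail(0.85), 0.85, tolerance = 0.05)
  expect_lt(sim_tail(0.85), 1)
})

test_that("resolution follows the Gaussian width identity", {
  p <- bare_peak(10, 0.1)
  expect_equal(resolution(p, bare_peak(10, 0.1)), 0)
  sigma <- 0.05
  w <- 2 * sqrt(2 * log(2)) * sigma
  r6 <- resolution(bare_peak(10, w), bare_peak(10 + 6 * sigma, w))
  expect_equal(r6, 1.5, tolerance = 0.05)
  # default simulated library peaks are all baseline-resolved
  ch <- simulate_injection(make_standard_series()$C4,
                           profile = noiseless_profile())
  tab <- process_chromatogram(ch)
  expect_true(all(tab$resolution[-1] >= 1.5))
})

test_that("analyte assignment fixes the reference and matches RRT windows", {
  ch <- simulate_injection(make_standard_series()$C4,
                           profile = noiseless_profile())
  tab <- process_chromatogram(ch)
  expect_setequal(tab$analyte, analytes())
  i6 <- match("PQ-6", tab$analyte)
  expect_identical(tab$rrt[i6], 1)
  expect_identical(tab$rpa[i6], 1)
  # recovered RRTs match the library within one sampling interval
  lib <- default_rrt_library()
  for (k in seq_len(nrow(tab))) {
    expect_lt(abs(tab$rrt[k] - lib$expected[lib$analyte == tab$analyte[k]]),
              0.01 / 35 + 1e-9)
  }
})

test_that("assignment tie-breaks and windows behave as documented", {
  mk <- function(rrt, area) bare_peak(rrt * 35, 0.12, area = area)
  # exact midpoint of the PQ-5 (0.72) and PQ-4 (0.75) windows -> PQ-5
  peaks <- list(mk(0.45, 900), mk(0.735, 800), mk(1.0, 5000))
  tab <- assign_analytes(peaks)
  expect_equal(tab$analyte[tab$rt_min == 0.735 * 35], "PQ-5")
  # outside every window -> unassigned
  peaks2 <- list(mk(0.45, 900), mk(0.60, 800), mk(1.0, 5000))
  tab2 <- assign_analytes(peaks2)
  expect_true(is.na(tab2$analyte[tab2$rt_min == 0.60 * 35]))
  # no plausible reference -> error
  expect_error(assign_analytes(list()), "reference peak not found")
})

test_that("assignment is invariant to input peak order", {
  ch <- simulate_injection(make_standard_series()$C2,
                           profile = noiseless_profile())
  bl <- estimate_baseline(ch)
  apexes <- detect_peaks(ch, baseline = bl)
  peaks <- lapply(apexes$index, integrate_peak, chrom = ch, baseline = bl)
  t1 <- assign_analytes(peaks)
  set.seed(1)
  t2 <- assign_analytes(sample(peaks))
  expect_equal(t1$analyte, t2$analyte)
  expect_equal(t1$area, t2$area)
})
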