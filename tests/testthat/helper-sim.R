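# Shared simulation fixtures, built in code.

noiseless_profile <- function(...) instrument_profile(noise_sd = 0, ...)

# a bare synthetic Gaussian trace (not via the simulator) for
# integration-level checks
gaussian_trace <- function(center = 2, sigma = 0.05, area = 1000,
                           t_max = 4, dt = 0.01, offset = 0) {
  tt <- seq(0, t_max, by = dt)
  chromatogram(tt, offset + area * dnorm(tt, center, sigma))
}

# a peak object with just the geometry fields, for metric unit tests
bare_peak <- function(t_r, width_half, area = 1, height = 1) {
  structure(list(t_r = t_r, width_half = width_half, area = area,
                 height = height, snr = Inf,
                 start = t_r - 3 * width_half, end = t_r + 3 * width_half,
                 plates = NA_real_, tailing = NA_real_,
                 resolution = NA_real_),
            class = "peak")
}

batch_fixture <- function() load_fixture("batch_contents")
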