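# Baseline run configuration: the defaults of the validated reference
# method. Units: min, ug/mL, detector units.

[simulator]
reference_rt = 35.0   # PQ-6 apex, min
width_half = 0.12     # half-height peak width, min
tailing = 1.0         # USP tailing target (1 = Gaussian)
noise_sd = 1.0        # baseline white-noise SD, detector units
drift = 0.0           # baseline drift, detector units per min
dt = 0.01             # sampling interval, min
run_length = 55.0     # run length, min

[peaks]
min_snr = 10
rrt_tolerance_multiplier = 2

[analysis]
linkage_variant = D2
hca_standardize = false
pca_mode = QAMS
alpha = 0.05
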