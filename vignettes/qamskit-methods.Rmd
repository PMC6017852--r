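---
title: "Single-marker quantitation and chemometric batch QC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantitation and chemometric batch QC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qamskit)
```

# The problem

Kumu injection (KMI) is a herbal preparation from *Picrasma quassioides*
whose activity is carried by six beta-carboline and canthinone alkaloids,
PQ-1 through PQ-6. Routine external-standard quantitation (ESM) needs six
reference standards per run. The single-marker approach (QAMS,
"quantitative analysis of multi-components by single marker") calibrates
only the abundant, stable marker nigakinone (PQ-6) and converts the other
five peak areas to concentrations through pre-established **relative
correction factors**

$$ f_x \;=\; \frac{A_s / C_s}{A_x / C_x}, $$

the ratio of the marker's response factor (area per concentration) to the
analyte's, measured from mixed standards where both concentrations are
known. Quantitation inverts this definition exactly:

$$ C_x \;=\; f_x \,\frac{C_s}{A_s}\, A_x , $$

with $A_s$, $C_s$ taken from the *same run's* PQ-6 peak ($C_s$ via the
marker's own calibration curve), so one standard calibrates the whole
chromatogram. Some published statements of the quantitation formula divide
by $f_x$ instead; substituting one printed equation into the other then
fails to return $C_x$. qamskit implements the algebraically consistent
multiplicative form above (it is the exact inverse of the definition, and
it is the form that makes QAMS agree with ESM on the packaged batch
table); the division form is available as `form = "printed"` purely for
comparison.

Identification is by **relative retention time** (RRT, retention over the
PQ-6 retention): 0.45 (PQ-1), 0.72 (PQ-5), 0.75 (PQ-4), 0.83 (PQ-3), 1
(PQ-6, by definition), 1.18 (PQ-2).

# Pipeline and containers

* `simulate_injection()` — chromatogram with known ground truth
  (`injection_spec`, `response_model`, `instrument_profile`).
* `estimate_baseline()`, `detect_peaks()`, `integrate_peak()`,
  `assign_analytes()` / `process_chromatogram()` — peak table with
  system-suitability metrics (`plates()`, `tailing_factor()`,
  `resolution()`).
* `fit_calibration()`, `esm_quantify()`, `lod_loq()` — ESM.
* `rcf_estimate()`, `single_marker_sample_quant()`, `compare_methods()` —
  QAMS and the ESM/QAMS paired comparison.
* `rsd()`, `replicate_assessment()`, `recovery_test()` — method
  validation.
* `standardize()`, `hca_ward()`, `cut_tree()`, `pca()`, `radar_table()` —
  batch classification.
* `load_fixture()` — the published reference tables (calibration curves,
  six-level RCFs, robustness grid, 20-batch contents) at full printed
  precision.

# The simulator: a stated world

The generator emulates the validated reference system, and its defaults
*are* that system's stated conditions; they were chosen once and are not
tuned against test outcomes.

| parameter | default | why |
|---|---|---|
| run length / sampling | 55 min / 0.01 min | gradient window of the reference method; 0.01 min gives >20 samples across a peak |
| PQ-6 retention | 35 min | not published; only RRTs matter downstream, so the absolute anchor is a free simulator parameter inside the window |
| RRTs | 0.45, 0.72, 0.75, 0.83, 1, 1.18 | published typical values |
| half-height width | 0.12 min | places all six plate numbers inside the published 30,711–744,241 suitability range |
| tailing target | 1.0 | published range 0.81–1.19 brackets symmetric; shape is an exponentially modified Gaussian whose time constant is solved numerically so the USP tailing factor hits the target (mirrored in time for fronting; factors below 0.5 are unreachable for this shape family) |
| noise SD | 1.0 detector unit | keeps every analyte's S/N above 1000 at mid-range contents, matching the published suitability statement |
| response model | published slopes and intercepts per analyte | the linear calibration table is the forward model; areas that the line would make negative at very low content clip to zero |
| standard series | 6 levels, evenly spaced per analyte across the published working ranges | level concentrations are not published; even spacing is the conventional design |

Not emulated: gradient-elution physics, column chemistry, UV spectra (254
nm is metadata), carryover, injection-volume effects, co-elution. A green
simulation test therefore establishes numerical correctness of the
pipeline on resolved near-Gaussian peaks — not instrument realism.

The working ranges used by the standard series are the published
*solution-preparation* ranges (e.g. PQ-1 11.0–41.3, PQ-5 2.00–14.1
ug/mL), which differ slightly from the published *fitted linear ranges*
shipped on the calibration fixture (10.9–40.9, 1.5–14.1). Both are
carried as printed; no intent is guessed.

# Numerical choices

* **Baseline**: running median, 2-min window (much wider than a peak),
  `endrule = "median"`; noise SD is the MAD x 1.4826 of the residual
  after discarding points beyond five robust SDs (peak exclusion).
* **Detection**: local maxima with height ≥ `min_snr` x noise SD and
  topographic prominence at least the same threshold, so noise wiggles
  riding a peak do not split it but genuinely separated neighbours (a
  valley between them) are kept.
* **Integration**: apex-outward walk to the nearest valley or to baseline
  return at 0.5% of apex height; trapezoidal area on the
  baseline-subtracted signal; a peak still above that level at the trace
  edge is an error ("clipped"), not a number. Windows are half-open
  `[start, end)` on the grid; all times in minutes.
* **Suitability**: plates by the half-height formula with constant 5.54;
  USP tailing `W0.05/2f` (absent, not an error, when the 5% level is not
  reached); resolution `2 dt / (1.699 (w1 + w2))`.
* **Assignment**: the reference is fixed first. Unless an explicit
  reference time is given, every peak is tried as a provisional PQ-6 and
  the candidate admitting the largest one-to-one RRT-window matching
  wins, area breaking ties (the marker is among the most abundant peaks).
  Window half-widths default to twice the published RRT SDs. Competing
  matches resolve by smallest |RRT − expected|; an exact tie (quantized
  at 1e-9 to absorb floating-point jitter) goes to the smaller expected
  RRT — a peak exactly between the PQ-5 and PQ-4 windows is called PQ-5 —
  then to the earlier peak.
* **Calibration**: unweighted least squares on areas (closed form), R =
  Pearson correlation; LOD/LOQ at S/N 3 and 10 ignoring the intercept by
  default (signal-above-baseline convention; `use_intercept = TRUE`
  restores the full inverse). Published LOD/LOQ values are
  instrument-specific and are not acceptance targets here.
* **RCF aggregation**: arithmetic mean over levels; robustness grand mean
  over all instrument x column cells; RSD always uses the n−1 SD. These
  conventions reproduce the packaged summary rows exactly (one exception
  below).
* **Pair SD** in the ESM/QAMS comparison is the sample SD of the two
  values, |ESM − QAMS|/sqrt(2), which reproduces the packaged 0.01/0.02
  column; the paired t-test is two-tailed, alpha 0.05, no multiplicity
  correction.
* **Recovery**: marginal convention, 100 (found − base)/added, spikes at
  80/100/120% of base content, two replicates per level (n = 6); the
  total-found convention is a flag. A blank base requires explicit added
  amounts. In the noiseless, intercept-free configuration recovery is
  exactly 100% — the truncation biases of integration cancel between
  calibration and quantitation because both come from the same pipeline.

# Chemometrics: what reproduces and what does not

`hca_ward()` implements Ward's minimum-variance agglomeration through the
Lance–Williams recurrence (variant "D2": updates on squared Euclidean
distances, square-rooted heights, equivalent to the classical Ward on
Euclidean input; variant "D" applies the same coefficients to plain
distances). Tests verify the merge sequence against a from-scratch
centroid-cost oracle and the heights against the standard implementation.
`pca()` eigendecomposes the correlation matrix; explained variance is
eigenvalue over number of analytes; the sign convention (dominant loading
entry positive) makes plots reproducible; tests verify eigenvalues
against an independent Jacobi rotation solver.

Three findings from the packaged 20-batch table deserve honesty:

1. **Grouping.** The published three-group batch partition ({S1–S6},
   {S7–S14}, {S15–S20}) reproduces robustly with Ward on the **raw**
   content matrix — under both Ward variants, plain or squared distances,
   ESM or QAMS values. On the **z-scored** matrix it does not: the two
   merge heights that decide the S19/S20 membership differ by less than
   0.02% (3.4703 vs 3.4709), and the two-decimal rounding of the packaged
   table flips the merge, moving S19/S20 into the first group. The
   original analysis reports standardizing; its unrounded data evidently
   fell on the other side of this knife edge. `hca_ward()` therefore
   defaults to the raw matrix (which reproduces the published result) and
   exposes `standardize = TRUE`; the flipped behaviour is pinned by a
   regression test. Correlation-matrix PCA is unaffected (it standardizes
   internally and is scale-free).
2. **Variance split.** PC1 explains 56.79% and PC1+PC2 85.49% of the
   variance, matching the published 56.8% / 85.5%.
3. **PC2 loadings.** The published discussion names PQ-1, PQ-3 and PQ-6
   as the high-loading analytes on PC2. From the packaged matrix the
   |PC2| ranking is PQ-6 (0.59) > PQ-3 (0.55) > PQ-4 (0.36) > PQ-2 >
   PQ-5 > PQ-1 (0.18): PQ-1 is the *smallest*. The published loading plot
   appears to come from a separate rotated factor analysis, which is out
   of scope here; tests assert only PQ-6 and PQ-3 among the top PC2
   loadings.

# Known limitation: intercepts make the RCF concentration-dependent

With the published response lines, the per-level factor is
$f(C) = (a_6 + b_6/C_6)/(a_x + b_x/C_x)$: the intercepts make $f$ drift
across the standard series, and a level-averaged $f$ is slightly wrong at
range-edge sample contents. In this package's synthetic world the bias
reaches −5.2% (PQ-1 near 12 ug/mL) and +3.8% (PQ-5 near 8 ug/mL) with
zero noise — larger than in the original measured data, whose published
six-level RCF columns are much tighter (RSD 1.8–3.3%) than the response
lines imply at evenly spaced levels. The actual level concentrations were
never published, so this gap is not recoverable; the end-to-end
recovery test states the stricter 2%/5% bounds and fails them honestly
rather than widening them. Practical upshot: QAMS with a mean RCF is
accurate to a few percent near mid-range and degrades toward range edges
exactly as the intercept-to-signal ratio grows; with intercept-free
responses it is exact (a property the tests verify).

# Reproducing the packaged results

```{r, eval = FALSE}
# RCF summary, robustness grand means, batch summary, grouping, PCA:
qams_cli(c("reproduce"))
# acceptance report:
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
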