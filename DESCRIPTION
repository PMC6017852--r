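Package: qamskit
Title: Single-Marker Quantitation and Chemometric Quality Assessment for
    Multi-Alkaloid HPLC Data
Version: 0.1.0
Authors@R:
    person("Qamskit", "Developers", email = "qamskit@example.org",
           role = c("aut", "cre"))
Description: Tools for quality assessment of the six-alkaloid Kumu
    (Picrasma quassioides) injection preparation by HPLC-UV: a
    chromatogram simulator with known ground truth, peak detection and
    integration with system-suitability metrics, retention-time-based
    analyte assignment, external-standard calibration with LOD/LOQ,
    single-marker quantitation via relative correction factors (QAMS)
    against the nigakinone (PQ-6) reference peak, analytical method
    validation statistics (stability, precision, repeatability,
    reproducibility, recovery), and chemometric batch classification by
    Ward hierarchical clustering, radar-table summaries and
    correlation-matrix principal component analysis. Ships the reference
    tables of the validated method (calibration curves, relative
    correction factors, robustness grid, 20-batch contents) as plain-text
    fixtures and a command-line interface chaining the stages end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
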