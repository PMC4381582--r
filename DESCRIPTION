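Package: mycSynLeth
Title: Synthetic-Lethality Analysis for Paired-Line Kinome RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for kinome-wide siRNA viability screens run in
    paired cell-line clones (e.g. a c-Myc-overexpressing clone against its
    empty-vector control): per-plate surviving-fraction normalization against
    non-targeting control wells, median-centered robust z-scoring, gene-level
    aggregation across siRNA duplexes, and concordance-based synthetic-lethality
    hit calling with a selectivity filter. Companion assays from the same
    validation workflow are covered: residual kinase activity from radiometric
    counts with four-parameter logistic (variable slope) IC50 fitting and
    bootstrap confidence intervals, delta-delta-Ct relative quantification
    against housekeeping genes, and chick chorio-allantoic membrane xenograft
    tumor-volume growth analysis from caliper diameters. Seeded synthetic-data
    generators reproduce the statistical structure of each assay so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
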