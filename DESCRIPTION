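Package: stretchmiR
Title: miRNA-mRNA Anti-Correlation Integration for Cyclically Stretched
    Alveolar Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for integrating miRNA microarray expression
    with a parallel mRNA differential-expression study in cyclically
    stretched alveolar epithelial cells: detection filtering, MA-loess
    normalization against a median pseudo-reference array, one-way ANOVA
    with pooled-variance pairwise contrasts, Benjamini-Hochberg step-up
    FDR, fold-change calling, dual-database target-prediction consensus
    with a context-percentile cutoff, anti-correlated miRNA:mRNA pairing,
    promiscuity and redundancy network summaries, and EASE-score
    (jackknifed one-sided Fisher exact) pathway over-representation
    against a custom background. Includes a synthetic-data generator with
    planted truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
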