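Package: pnimeta
Title: Multi-Cohort Differential Expression Meta-Analysis for Cancers
    with Perineural Invasion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analysis of tumor-versus-control microarray
    cohorts from cancers with a high incidence of perineural invasion.
    Implements empirical-Bayes moderated t-statistic differential
    expression with Benjamini-Hochberg adjustment, a group-composition
    equalization (resampling) robustness check for unbalanced designs,
    within-cancer and cross-cancer intersection of differentially
    expressed genes, cross-referencing against neurodevelopmental and
    axon-guidance gene signatures with paralog-family collapse,
    hypergeometric over-representation analysis, quantile-normalization
    and k-means clustering quality control, and survival stratification
    by single genes or combined paralog-family scores with a
    best-cutoff log-rank scan and permutation adjustment. Ships a
    synthetic-data generator with planted ground truth so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
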