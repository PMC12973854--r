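Package: mrcausal
Title: One- and Two-Sample Mendelian Randomization with Polygenic Risk
    Score and Summary-Statistic Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete Mendelian randomization (MR) workflow
    for binary exposures and bounded continuous outcomes: selection of
    genome-wide-significant instruments from GWAS summary statistics with
    PLINK-style greedy linkage-disequilibrium clumping, allele
    harmonization across exposure and outcome datasets, a one-sample
    polygenic-risk-score two-stage least-squares estimator with
    F-statistic weak-instrument gating and PRS-tertile descriptive
    tables, and summary-statistic estimators (inverse-variance weighted,
    MR-Egger with the I2GX regression-dilution gate, and the weighted
    median with parametric-bootstrap standard errors) together with
    funnel-plot outlier detection and leave-one-out sensitivity
    analyses.  A seeded synthetic-cohort generator produces LD-structured
    genotypes, a liability-threshold binary exposure and an MMSE-like
    outcome with configurable causal effect, confounding and horizontal
    pleiotropy, so the whole pipeline is testable end to end without
    access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
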