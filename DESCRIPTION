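Package: bmimr
Title: Mendelian Randomization Pipeline for Adiposity and Depression with
    Synthetic Biobank Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Mendelian randomization (MR) analyses of a continuous
    exposure (body mass index) on a binary outcome (depression), mirroring the
    design of large biobank studies. Builds weighted genetic risk scores with
    allele-count rescaling, runs one-sample two-stage instrumental-variable
    analysis with a logistic second stage and robust standard errors, and
    two-sample summary-statistic estimators (inverse-variance weighted,
    MR-Egger, weighted and penalized weighted median) with heterogeneity
    diagnostics. Includes allele harmonization for GWAS summary statistics,
    Fisher z comparison of stratified estimates, fixed-effect meta-analysis,
    over-identification tests between instrument subsets, a per-variant
    pleiotropy screen, negative-control batteries, and a calibrated synthetic
    cohort generator that emulates the statistical structure of a biobank-scale
    case-control analysis so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
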