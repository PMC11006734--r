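Package: sexdiffmeth
Title: Sex-Differential DNA Methylation Meta-Analysis Across Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for epigenome-wide analysis of sex
    differences in DNA methylation across several pregnancy cohorts:
    per-CpG Huber robust regression of M-values with
    heteroskedasticity-consistent (White) standard errors, empirical-null
    estimation of bias and inflation of test statistics via a
    three-component Gaussian mixture, DerSimonian-Laird random-effects
    meta-analysis, correlation-aware differentially methylated region
    calling (Stouffer-Liptak-Kechris combination with a 200-bp extension
    rule), cis-meQTL mapping with sex-consistent versus sex-specific
    classification, Fisher enrichment against the tested-but-not-significant
    background, cross-tissue effect-size comparison, and summary-level
    cohort demographics tests. Includes a synthetic multi-cohort generator
    with planted ground truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    metafor,
    sandwich,
    optparse
Config/testthat/edition: 3
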