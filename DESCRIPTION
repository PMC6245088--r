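Package: mrtwosample
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and harmonizing SNP association tables (allele
    alignment, strand complements, palindromic-SNP filtering, proxy
    substitution), per-SNP Wald-ratio causal estimates with delta-method
    standard errors, inverse-variance-weighted and maximum-likelihood
    combining with Student-t inference, pleiotropy-robust sensitivity
    estimators (MR-Egger regression, weighted median with parametric
    bootstrap), Cochran's Q / I-squared heterogeneity and leave-one-out
    diagnostics, instrument-strength measures (R-squared, F-statistic,
    I-squared-GX), power calculations for binary outcomes, a Bonferroni
    phenome-screen, and a seeded generator of synthetic two-sample summary
    statistics for estimator calibration. Includes an executable case study
    estimating the causal effect of serum calcium on overall and advanced
    prostate cancer risk from a five-SNP instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
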