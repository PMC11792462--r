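Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    microbiome-to-disease analyses with metabolite mediation. Provides
    readers and writers for GWAS summary statistics, allele harmonization
    with palindromic-variant handling, greedy LD clumping, instrument
    selection with F-statistic filtering and confounder exclusion, the
    inverse-variance-weighted, weighted-median and MR-Egger estimators with
    Wald-ratio fallback, a sensitivity battery (Cochran's Q, MR-Egger
    intercept, MR-PRESSO outlier detection, leave-one-out), mediation
    analysis via two-step MR and multivariable MR with
    mediation-versus-suppression classification, and a summary-level
    simulator with known causal structure for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
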