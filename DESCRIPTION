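Package: clockmr
Title: Bidirectional Two-Sample Mendelian Randomization for Epigenetic
    Aging and Kidney Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization
    (MR) between epigenetic age acceleration and kidney-function traits,
    usable for any exposure-outcome pair supplied as GWAS summary
    statistics.  Covers reading and validating summary-statistic tables,
    allele harmonization with palindromic-variant resolution, genetic
    instrument construction (significance filtering, greedy LD clumping,
    exclusion lists, dual-marker refinement, Steiger filtering,
    instrument-strength diagnostics), causal estimation by Wald ratio,
    inverse-variance weighted, MR-Egger and weighted-median methods with
    Rucker model selection, MR-PRESSO outlier detection, leave-one-out
    analysis, multivariable MR with difference-method mediation,
    individual-level allele-score MR with the CKD-EPI creatinine-cystatin
    eGFR equation, closed-form power analysis, a reporting pipeline with
    false-discovery-rate control, and a fully seeded synthetic-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
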