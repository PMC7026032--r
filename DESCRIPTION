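Package: grsmr
Title: Mendelian Randomisation with Unweighted Genetic Risk Scores on
    Individual-Level Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-sample Mendelian randomisation for biobank-style cohorts
    using unweighted genetic risk scores as instruments. Provides a
    synthetic-cohort generator with Hardy-Weinberg genotypes, shared-factor
    exposure correlation, unmeasured confounding and optional pleiotropic
    instruments; questionnaire phenotype derivation (EPQ-N neuroticism,
    education leaving age, IPAQ MET-minutes); per-variant quality control
    and risk-score construction; observational least squares, two-stage
    least squares and multivariable MR estimators with corrected standard
    errors, first-stage and Sanderson-Windmeijer conditional F diagnostics;
    per-variant instrument-validity screening; analytic power calculation
    for MR with a continuous outcome; and a reproducible end-to-end
    pipeline driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
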