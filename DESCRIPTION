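Package: brainvuln
Title: Brain Structural Vulnerability Indices from Meta-Analytic Deficit Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes individual-level indices of brain structural vulnerability
    from regional neuroimaging phenotype tables: the meta-analytic dot product
    index (a normalized dot product between a subject's covariate-adjusted,
    inverse-normal-transformed regional deviation vector and a consortium-derived
    case-control effect-size vector) and the quantile regression index of
    deviation from normative aging (regional -1/0/+1 scores against fitted 5th
    and 95th age-conditional percentiles, averaged per tissue and whole-brain).
    Includes group-severity and cognition pattern-matching analyses, a seeded
    synthetic cohort generator for end-to-end validation, and a reproducible
    pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quantreg,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
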