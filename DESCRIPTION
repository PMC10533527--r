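Package: svbn
Title: Bayesian Network Risk Analysis for Single-Ventricle CHD Outcome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network analysis of neurodevelopmental and
    growth outcomes in single-ventricle congenital heart disease cohorts.
    Provides cohort table ingestion and threshold-based dichotomization,
    exact BIC-optimal structure learning by dynamic programming over
    variable subsets, conditional-probability queries by variable
    elimination (with a brute-force enumeration oracle), relative-risk
    ratio queries with percentile bootstrap confidence intervals over
    relearned networks, ROC-AUC-driven cutoff selection for continuous
    outcomes, Mann-Whitney group comparisons with Bonferroni correction,
    and a synthetic cohort generator with known ground-truth networks for
    validation without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
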