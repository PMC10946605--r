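Package: msmtrial
Title: Marginal Structural Cox Models for Target-Trial Emulation in
    Multiple Sclerosis Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating per-protocol effects of disease-modifying
    therapy from longitudinal multiple sclerosis registry data using marginal
    structural Cox models. Derives 12-month-confirmed disability worsening and
    improvement events from Expanded Disability Status Scale trajectories,
    discretises follow-up into 6-month treatment/covariate panels under three
    target-trial emulation designs, computes stabilized inverse-probability-of-
    treatment weights from pooled logistic treatment models, and fits weighted
    Cox proportional-hazards models with cluster-robust variance, including
    treatment-by-modifier interactions, stratified effects, and three-way
    phenotype-by-relapse-rate terms. A synthetic registry generator with
    confounding by indication and known ground-truth hazard ratios supports
    validation by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    sandwich,
    stats,
    survival,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
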