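Package: msmwave
Title: Marginal Structural Models for Longitudinal Claims Panels
Version: 0.1.0
Authors@R:
    person("msmwave", "maintainers", email = "maintainers@msmwave.example", role = c("aut", "cre"))
Description: Tools for estimating the causal effect of a time-varying binary
    exposure on claims-based health outcomes with marginal structural models.
    Provides a synthetic claims-style cohort generator with known causal
    structure (treatment-confounder feedback, informative censoring), a wave
    panel builder with interval aggregation and percentile-based exposure
    assignment, Elixhauser comorbidity and ambulatory-care-sensitive-condition
    coding from diagnosis codes, stabilized inverse-probability-of-treatment
    and censoring weights with truncation, standardized-mean-difference balance
    diagnostics, weighted pooled outcome models with cluster bootstrap
    confidence intervals, and an exact g-formula oracle on small discrete
    worlds for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
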