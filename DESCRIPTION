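Package: tailoras
Title: Tailored Active-Surveillance Biopsy Rules under Interval Censoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation and evaluation of individualized active-surveillance
    biopsy strategies when disease progression is interval-censored and
    patients drop out immediately after a positive biopsy. Provides
    nonparametric kernel estimators of time-varying true positive and true
    negative rates built from adjacent negative-positive biopsy pairs, a
    weighted-benefits value function with a cost-benefit trade-off, and a
    surrogate-loss weighted-classification learner (OSF-I) for stabilized
    linear surveillance rules, together with a fully specified cohort
    simulator and inverse-probability-of-censoring-weighting and
    current-status comparators for bias and policy-value studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
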