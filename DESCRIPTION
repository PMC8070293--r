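Package: marsurv
Title: Direct Modelling of Marginal Relative Survival with Time-Dependent
    Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of marginal (net) relative survival from
    registry-style cohort data and population lifetables.  Implements a
    flexible parametric model on the log cumulative excess hazard scale
    that estimates marginal relative survival directly through a weighted
    likelihood with time-dependent inverse-expected-survival weights and
    a cluster-robust sandwich variance, together with the non-parametric
    Pohar Perme estimator (internally or externally age-standardized),
    conditional flexible parametric excess hazard models with regression
    standardization, lifetable utilities, and a simulation harness for
    comparing the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    stats,
    utils
Suggests:
    flexsurv,
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
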