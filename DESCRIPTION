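Package: aaamonitor
Title: Bayesian Hierarchical Growth Models for Aneurysm Surveillance
    Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian hierarchical growth-curve models (linear,
    quadratic, covariate-adjusted, independent-intercept, Student-t error
    and left-censored variants) to longitudinal abdominal aortic aneurysm
    diameter series by blocked Gibbs sampling; makes individual-level
    predictions of growth rate, time to a surgical threshold and future
    measurements under cut semantics; and converts exceedance
    probabilities of the posterior predictive distribution into
    rescan-interval recommendations for screening programmes.  Includes a
    synthetic cohort generator emulating a national aneurysm screening
    study so that every stage is testable without access to patient data.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
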