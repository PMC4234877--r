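Package: eq5dmap
Title: Mapping EORTC QLQ-C30 Domain Scores onto EQ-5D-3L Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for crosswalking the cancer-specific EORTC QLQ-C30
    quality-of-life questionnaire onto EQ-5D-3L preference-based utilities.
    The core estimator is a zero-one-inflated beta regression with a logit
    mean submodel and a log dispersion submodel, fitted by maximum
    likelihood, with an optional subject-level random intercept.  Five
    benchmark mapping estimators (linear mixed, two-limit tobit, quadratic,
    quantile/LAD and censored least absolute deviation) share a common
    fit/predict contract.  The package also provides the UK TTO tariff for
    EQ-5D-3L health states, a Fleishman/Vale-Maurelli simulator for
    correlated non-normal trial data, a validation battery (RMSE, MAE, R2,
    out-of-range accounting, prediction bands, health-state-ordered
    prediction curves, Monte-Carlo confidence-interval coverage), and
    QALY estimation with probabilistic sensitivity analysis under
    exponential survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nnet,
    pracma,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    Matrix,
    knitr,
    rmarkdown
Config/testthat/edition: 3
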