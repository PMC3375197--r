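Package: bmitraj
Title: Childhood BMI Trajectory Modelling with Fractional-Polynomial Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models childhood body mass index (BMI) trajectories from 1 week to
    18 years of age using fractional-polynomial linear mixed-effects models with
    structured within-child residual covariance. Enumerates the candidate
    fractional-polynomial model space, performs two-stage BIC selection of the
    residual covariance and mean structures, predicts individual-specific curves
    from fixed effects plus best linear unbiased predictions of random effects,
    detects the infancy BMI peak and adiposity rebound by a grid-based
    derivative sign-change rule, and derives trajectory characteristics
    (BMI change, velocity, age difference, area under the curve). Includes
    preprocessing for well-child-visit anthropometry (recumbent-length
    correction, BMI computation, visit-schedule eligibility, internal
    birth-weight z-scores), a seeded synthetic-cohort simulator emulating
    pediatric visit schedules and the measurement process, and a downstream
    correlation and regression stage for trajectory characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
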