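Package: crosslag
Title: Simulation and Unbiased Estimation for Cross-Lagged Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying covariate endogeneity in multi-subject
    biological time series. Simulates cross-lagged data-generating processes
    (life-history trade-offs, density dependence of vital rates, benefits of
    group living) with among-subject random-intercept covariance and optional
    measurement error; fits static mixed models, lagged-dependent-variable
    models, dynamical structural equation models with correlated random
    intercepts, and an errors-in-variables extension with known measurement
    error variances; runs Monte-Carlo bias and power experiments over grids of
    subject number and time-series length; provides empirical cross-lag
    diagnostics; and includes a Bayesian Poisson/binomial pipeline for
    cooperative-breeding group panels together with a synthetic group-dynamics
    generator for testing it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
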