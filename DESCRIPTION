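Package: trajmix
Title: Sigmoidal and Random-Changepoint Mixed Models for Longitudinal Data via SAEM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three interpretable nonlinear mixed-effects models for
    continuous longitudinal outcomes: a four-parameter sigmoidal (logistic)
    mixed model, a piecewise linear mixed model with an abrupt subject-specific
    changepoint, and a piecewise model with a smooth cubic-polynomial
    transition between the two linear phases. Estimation is by a Stochastic
    Approximation EM (SAEM) algorithm with Metropolis-Hastings conditional
    simulation of the random effects, Louis-type standard errors, Wald tests
    for all fixed effects, and an importance-sampling marginal log-likelihood.
    Includes automated data-driven initial values, covariate effects on all
    four structural parameters, marginal-trajectory summaries and plots, and a
    simulator for decedent-style visit schedules with sigmoid or broken-stick
    trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
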