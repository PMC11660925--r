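Package: msphase
Title: Multiple Sclerosis Phenotype Classification and Multi-State
    Transition Modelling for Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal multiple sclerosis registry data:
    day-resolution classification of disease phenotype (relapsing-remitting,
    relapsing and non-relapsing secondary progressive) from physician
    diagnosis dates and relapse histories using a two-year retrospective
    relapse window; a continuous-time multi-state Markov model for
    panel-observed phenotype transitions with transition-specific fixed and
    time-varying covariate effects, fitted by maximum likelihood with
    matrix-exponential transition probabilities; predicted transition
    probabilities with simulation-based confidence intervals and
    observed-versus-expected prevalence goodness of fit; supporting
    estimators (Aalen-Johansen cumulative incidence under competing risks,
    Kaplan-Meier, Cox proportional hazards for disability milestones,
    Poisson relapse rates with robust variance, GEE Poisson relapse-rate
    trajectories); and a synthetic registry generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    graphics,
    Rcpp,
    jsonlite,
    sandwich,
    stats,
    survival,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
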