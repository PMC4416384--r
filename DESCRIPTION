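Package: htbpkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of the
    Triflusal Metabolite HTB with a Binary Platelet-Aggregation Endpoint
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects (population) pharmacokinetic and
    pharmacodynamic modelling of 2-hydroxy-4-(trifluoromethyl) benzoic
    acid (HTB), the active metabolite of the antiplatelet drug triflusal.
    Implements a one-compartment model with first-order metabolite
    formation and allometric weight covariates, Laplace (FOCE-style)
    marginal-likelihood estimation with empirical Bayes estimates and
    shrinkage, a binary-probability Hill pharmacodynamic model for
    dichotomized platelet aggregation, an indirect-response (turnover)
    simulator, covariate screening, likelihood-ratio testing, visual
    predictive checks, nonparametric bootstrap, derived exposure metrics
    (steady-state trough, accumulation factor), a NONMEM-style dataset
    reader/writer, and a seeded virtual-trial generator reproducing the
    study design (34 subjects, 476 concentration and 340 aggregation
    records).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
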