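Package: twostagepk
Title: Two-Stage Bayesian Hierarchical Pharmacokinetics of Subcutaneous Insulin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian hierarchical nonlinear mixed-effects models to
    meal-window plasma insulin concentration profiles from continuous
    subcutaneous insulin infusion (CSII) trials. A two-compartment absorption
    model with a linear residual-insulin term is fitted per profile by
    adaptive Markov chain Monte Carlo under flat priors (stage 1); the stored
    posterior draws then serve as Metropolis-Hastings independence proposals
    in a full hierarchical model (stage 2) with one-, two- and three-level
    population structures, reversible-jump covariate selection with grouped
    priors, and leave-one-profile-out model criticism via predictive-prior
    Bayesian p-values. Includes a synthetic trial generator emulating a
    22-woman, two-visit, two-meal CSII study design for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
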