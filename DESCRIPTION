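Package: msoccu
Title: Bayesian Multistate Occupancy Models for Camera-Trap Detection Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits Bayesian multistate (three-state) occupancy models to
    detection histories from repeated surveys such as monthly camera-trap
    occasions, where sites may be unoccupied, occupied by adults only, or
    occupied by adults with young.  Implements the multinomial detection
    formulation with no false positives and one-way misclassification of the
    highest state, logit-linear submodels for occupancy, conditional
    reproduction and detection with site-level random effects, posterior
    sampling by latent-state augmentation with blockwise random-walk
    Metropolis updates, Gelman-Rubin convergence diagnostics, derived
    occupancy-state counts, covariate-response predictions with credible
    bands, and a synthetic-data generator for design-based simulation and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
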