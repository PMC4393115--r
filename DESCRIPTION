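Package: seqsmlm
Title: Sequential Single-Fluorophore Super-Resolution Imaging Toolkit
Version: 0.1.0
Authors@R:
    person("seqsmlm", "developers", email = "seqsmlm@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for sequential single-molecule
    localization microscopy (dSTORM) in which multiple cellular targets are
    imaged one after another with the same fluorophore. Provides a blinking
    emitter and camera simulator, maximum-likelihood Gaussian PSF fitting
    under a Poisson noise model with Cramer-Rao lower bound precisions and
    likelihood-ratio goodness-of-fit filtering, fiducial-free brightfield
    z-stack registration and stage stabilization by normalized
    cross-correlation, precision-weighted super-resolution reconstruction
    and multi-color overlay composition, and estimators for inter-round
    cross-talk and global/local overlay shifts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
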