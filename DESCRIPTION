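Package: nocidetect
Title: Drift-Diffusion and Hazard Models of Nociceptive Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational models of Adelta-fiber-mediated detection of
    electrocutaneous pulse-train stimuli. Implements a stochastic
    drift-diffusion model (Euler-Maruyama simulation of a lumped leaky
    integrator with additive white noise) and a probabilistic hazard model
    (inhomogeneous-Poisson escape noise on the noise-free postsynaptic
    potential), peripheral strength-duration fiber recruitment, psychometric
    curves with exact binomial confidence intervals, joint fitting of the
    hazard model to drift-diffusion curves, a Monte Carlo parameter-space
    study of the fitting error, and detection-threshold computations
    including the two-pulse probability-summation asymptote and
    inter-pulse-interval sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
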