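Package: swayid
Title: Closed-Loop System Identification of Human Stance Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying standing balance as a closed feedback loop.
    Generates pseudorandom ternary support-surface perturbations, simulates
    an independent-channel inverted-pendulum stance model (PD controller,
    lumped delay, sensory weights, low-pass positive force feedback) in the
    time domain with pink sensory/motor noise, estimates frequency response
    functions and coherence from perturbation/sway recordings by periodic
    spectral averaging, and re-estimates the model parameters with a
    coherence- and frequency-weighted nonlinear least-squares fit, with
    variance-accounted-for and standard-error diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
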