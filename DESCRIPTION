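Package: subkinetics
Title: Kinetic Modelling of Subconductance Gating in Single-Channel Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying subconductance (sublevel) gating of
    single ion channels, motivated by sarcoplasmic-reticulum K+ (TRIC-B)
    channels. Builds aggregated Markov gating models with explicit
    subconductance classes or fast-flicker couplets, simulates continuous
    current traces with the Gillespie stochastic simulation algorithm
    through a realistic acquisition chain (Gaussian filtering, resampling,
    baseline noise), idealizes traces by segmental k-means, fits dwell-time
    exponential mixtures and dead-time-corrected rate constants by maximum
    interval likelihood, and discriminates competing gating schemes by the
    Earth Mover's Distance between amplitude distributions with
    multidimensional-scaling embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
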