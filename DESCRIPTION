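Package: columnet
Title: Mean-Field Simulation of Layered Cortical Columns for Top-Down
    Attention in the Gamma Band
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact mean-field simulation of a two-column, sixteen-population
    cortical microcircuit of quadratic integrate-and-fire (QIF) neurons with
    Lorentzian-distributed background currents. Provides the Lorentzian-ansatz
    firing-rate/mean-voltage reduction for every population, a forward-Euler
    integrator, stimulus conditions mimicking competing oriented-bar stimuli
    with top-down attention, envelope and amplitude-spectrum analysis,
    classification of oscillatory regimes (ordered pattern, winner-take-all,
    anti-winner-take-all, concurrent case), parameter-plane sweeps over
    population heterogeneity, structural ablations of layer 6 pathways, and a
    finite-size spiking QIF network used to validate the mean-field reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
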