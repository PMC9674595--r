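Package: hncstem
Title: Hierarchical Neutral Competition Models of Stem Cell Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and exact analysis of a multi-clone Moran-type model of
    tissue stem cell homeostasis in which a closed layer of K master stem cells
    supplies an open layer of N neutrally competing stem cells. The model
    interpolates between the classical hierarchical model (supply only), the
    neutral-competition model (competition only) and the intermediate
    hierarchical neutral competition (hNC) regime. Provides a fast stochastic
    simulator of clone dynamics, the closed-form stationary clone-size
    distribution and master-equation dynamics of a focal clone, first-passage
    theory of burst-like clonal expansions (generation probabilities and
    expected durations), scaling-law diagnostics of pulse-labeled clone-size
    distributions, Shannon-diversity statistics, and simulation-based
    estimation of the master-cell proliferation rate from clonal-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
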