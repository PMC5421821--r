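Package: eichaos
Title: Dynamical Mean-Field Theory and Simulation of Sparse Excitatory-Inhibitory Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing intrinsically generated fluctuating activity in
    sparsely connected excitatory-inhibitory networks of rate units and of leaky
    integrate-and-fire neurons.  Implements the dynamical mean-field (DMF)
    self-consistency equations for networks with threshold-linear or LIF
    transfer functions (fixed and stochastic in-degree, block two-population
    connectivity, external white noise and Poisson spiking noise), the
    random-matrix stability analysis of the homogeneous fixed point (bulk
    spectral radius and outlier eigenvalues), the two critical couplings that
    separate the fixed-point, inhibition-stabilized and bound-stabilized
    regimes, and fast compiled simulators for the corresponding rate, discrete
    and spiking network models, together with the empirical estimators
    (variance decomposition, autocorrelation, fluctuation timescale, filtered
    firing rates, synchrony index) needed to compare simulation to theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
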