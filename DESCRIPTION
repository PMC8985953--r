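Package: chromem
Title: Chromatin Modification Circuit Dynamics and Epigenetic Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reaction-network models of a gene's inner chromatin modification
    circuit: activating histone marks (H3K4me3/ac), repressive histone marks
    (H3K9me3) and DNA (CpG) methylation interacting through de novo
    establishment, auto- and cross-catalysis, and basal and recruited erasure.
    Provides deterministic mean-field (ODE) analysis with equilibrium,
    bifurcation, stability-chart and hysteresis tools; exact finite-state
    continuous-time Markov chain analysis (stationary distributions, mean
    first-passage times, one-dimensional model reduction by stochastic
    averaging, and closed-form small-epsilon limits); and a Gillespie
    stochastic simulation engine with first-passage and reactivation
    experiments. Circuit composition operators build TF-enabled positive
    autoregulation and mutual-repression gene network motifs on top of the
    core circuit.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
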