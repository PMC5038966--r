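Package: patterninfo
Title: Positional Information in Ising-Like Models of Morphogen Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much positional information a row of cells
    can extract from a noisy morphogen gradient when the readout is a set of
    binary ("ON/OFF") patterning genes with local and spatial interactions,
    modelled as a one-dimensional Ising chain in an inhomogeneous field.
    Provides exact transfer-matrix computation of per-site expression-state
    marginals and of the mutual information between position and expression
    state, exact-chain and Metropolis pattern samplers covering long-range
    couplings, simulated-annealing maximization of positional information over
    readout and coupling parameters, reference Counter and French Flag
    patterns, and robustness analyses (overlap under morphogen dosage
    perturbations, susceptibility, and system-size scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
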