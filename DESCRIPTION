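Package: spectralmap
Title: Slow Collective Variables from Molecular Dynamics by Spectral Gap Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns slow collective variables (CVs) from time-ordered
    molecular dynamics feature data by maximizing the spectral gap of a
    Markov transition matrix built from an anisotropic diffusion kernel
    with adaptive, sample-dependent scales. Includes kinetic
    coarse-graining of the transition matrix into metastable states and a
    transition-state ensemble, a Bayesian Markovianity test for
    one-dimensional reaction coordinates, coordinate-dependent diffusion
    coefficients, diffusion-corrected free-energy profiles, mean
    first-passage times with block-bootstrap confidence intervals,
    pairwise-distance and native-contact featurization, per-feature
    spectral-gap importance scores, and an overdamped Langevin simulator
    for generating ground-truth benchmark data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
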