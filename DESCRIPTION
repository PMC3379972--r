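Package: rangediv
Title: Dated Phylogenies, Ancestral Geographic Ranges and
    Range-Dependent Diversification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for historical biogeography on dated
    phylogenies: penalized-likelihood rate smoothing to convert phylograms
    into chronograms under a fixed crown calibration, with cross-validated
    choice of the smoothing level; the dispersal-extinction-cladogenesis
    (DEC) likelihood model for ancestral geographic ranges with maximum
    likelihood estimation of dispersal and local extinction rates;
    conversion of per-node range reconstructions into dated dispersal and
    extinction event scenarios summarized through time and in time slices;
    and the geographic state speciation and extinction (GeoSSE) model with
    incomplete-sampling corrections, likelihood-ratio model comparison and
    Markov chain Monte Carlo posterior sampling. Simulators for birth-death
    trees, DEC range histories, GeoSSE tip states and autocorrelated
    substitution-rate variation provide ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
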