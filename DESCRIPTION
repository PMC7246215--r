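Package: beevolve
Title: Eco-Evolutionary Dynamics of Plant-Pollinator-Honey Bee Mutualisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a discrete-time, three-species mutualism between a
    plant, a wild pollinator, and a managed honey bee, with quantitative-
    genetics evolution of the mutualism investment traits of each species.
    Each trait raises the visitation rate between partners but linearly
    reduces its bearer's carrying capacity, so selection balances attraction
    against density-dependent cost. The package provides the one-step maps
    for abundances and traits, long-run simulators with equilibrium
    detection and regime classification, burn-in/invasion protocols for
    introducing the managed honey bee into a resident plant-wild-pollinator
    mutualism, parameter sweeps with preset scenarios, bisection search for
    coexistence/displacement boundaries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
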