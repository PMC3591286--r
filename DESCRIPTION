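Package: traplinesim
Title: Trapline Formation in Foraging Bees by Iterative Route Reinforcement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based simulation of trapline development by central-place
    foragers such as bumblebees. A model bee repeatedly leaves its nest,
    samples flower-to-flower transition vectors from a learned probability
    table initialised in inverse proportion to squared distance, and
    multiplicatively reinforces the vectors of any foraging bout no longer
    than the shortest route experienced so far. The package provides flower
    array generators and plain-text array files, exact shortest-circuit
    oracles (Held-Karp dynamic programming and brute-force enumeration),
    subset-optimal circuits for crop-limited foraging, the nearest-neighbour
    baseline, a pairwise-transposition route improvability test, route
    similarity and transition asymmetry indices, empirical rank p-values
    against simulated null distributions, a loop-search model of flower
    finding with its closed-form optimal loop scale, and named experiment
    recipes for cohort simulations across spatial configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
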