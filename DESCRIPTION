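Package: neurocable
Title: Compartmental Neuronal Network Simulation with Event-Driven Synapses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator for networks of morphologically detailed
    neurons. Discretizes branched neuron morphologies into compartmental trees,
    integrates the cable equation with an implicit (backward Euler) fixed step,
    solves the tree-structured membrane matrix by Hines Gaussian elimination at
    unbranched-cable cost, and couples cells through delayed event-driven
    synapses with minimum-delay spike exchange. Mechanisms (passive leak,
    Hodgkin-Huxley channels, exponential synapses, current clamps, gap
    junctions, stochastic stimulus sources) are stored in Structure-of-Arrays
    pools; node permutations (interleaved, constant-depth) and a parent-access
    locality metric model SIMD-friendly memory layouts. Models and simulator
    state serialize to deterministic on-disk archives supporting
    checkpoint-restart with undelivered-event collapsing, and all randomness
    flows through a counter-based generator for reproducible, partition-
    invariant streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
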