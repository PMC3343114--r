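Package: percap
Title: Storage Capacity of Excitatory and Bistable Perceptrons with
    Temporally Correlated Patterns
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how many input/output associations a
    threshold neuron with excitatory (nonnegative) synaptic weights can
    store when the inputs and target outputs are temporally correlated
    binary sequences generated by two-state Markov chains.  Provides
    correlated pattern generators with exact chain statistics, perceptron
    learning rules for standard and bistable (hysteretic) output units --
    including an error-driven state-switching rule and its
    no-state-switching control -- an exact convex-programming feasibility
    oracle for small instances, simulation-based estimation of the
    maximal storage capacity by bisection over the sequence length, a
    replica-symmetric theory solver for the capacity and the synaptic
    weight distribution of the bistable excitatory perceptron, and
    desk-scale experiment drivers with seeded, manifest-backed
    reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    quadprog,
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
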