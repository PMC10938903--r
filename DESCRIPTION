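Package: walkerbn
Title: Walker-Ensemble Dynamics and Perturbation-Response Measures for
    Boolean Networks
Version: 0.1.0
Authors@R:
    person("walkerbn", "developers", email = "walkerbn@example.org",
           role = c("aut", "cre"))
Description: Simulation and exact analysis of Boolean network models of
    regulatory systems.  Networks written as plain-text update rules are
    evolved as large ensembles of independent instances ("walkers") under
    synchronous or uniformly-random asynchronous update.  Matched
    perturbed/unperturbed trajectory pairs sharing one update schedule
    yield four perturbation-response measures: the Derrida coefficient,
    the final Hamming distance, the fragility, and the quasicoherence,
    each in fixed-source and perturbable-source variants.  A brute-force
    state-transition-graph oracle provides exact attractors,
    quasiattractors, basin sizes, absorption probabilities, and exact
    values of all measures on small networks.  Kauffman NK random
    Boolean network ensembles and source-node prevalence statistics are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
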