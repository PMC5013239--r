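Package: swarmselect
Title: Wrapper Gene Selection with Binary Quantum-Behaved Particle Swarm
    Optimization and Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects small, highly discriminative gene subsets from two-class
    expression matrices with a binary quantum-behaved particle swarm optimizer
    (BQPSO) wrapped around a radial-basis-function support vector machine
    scored by leave-one-out cross validation. Includes sigmoid binary PSO and
    canonical genetic algorithm baselines, a two-sample t-test prefilter that
    reduces the search space to the top-ranked genes, a synthetic two-class
    expression generator with planted informative genes, and a benchmark
    harness reporting best/mean/standard-deviation accuracy, mean subset size
    and gene selection frequencies over repeated stochastic runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
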