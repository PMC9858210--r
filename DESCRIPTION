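Package: markovfusion
Title: Markov Kernel Dynamics, Decorated Permutations, and Fusion Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Finite Markov kernel algebra for networks of interacting agents:
    validation and composition of row-stochastic kernels, communicating-class
    analysis, invariant measures, exact kernel flows, and idempotent (rank-one)
    fusion kernels on the polytope of stochastic matrices. Implements the
    projection of Markov chains, directed graphs, and full-rank Grassmannian
    matrices to decorated permutations, the bridge decomposition of decorated
    permutations into adjacent transpositions, construction and trip-reading of
    bicolored planar (plabic, on-shell) diagrams, and the conditional-entropy
    arrow of homogeneous chains started from a stationary distribution.
    Includes serialization (CSV, JSON, TSV edge lists, DOT diagrams), a seeded
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
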