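Package: codechron
Title: Complexity-Constrained Chronology of Amino Acid Recruitment
Version: 0.1.0
Authors@R:
    person("codechron", "maintainers", email = "codechron@example.org",
           role = c("aut", "cre"))
Description: Reconstructs a molecular-complexity-based chronology of amino
    acid recruitment into the standard genetic code. Builds amino-acid
    distance matrices from tables of graph-theoretic and information-theoretic
    complexity indices, embeds them with classical multidimensional scaling,
    derives an epsilon-neighborhood (Vietoris-Rips 1-skeleton) graph and its
    minimum spanning tree, and tests the tree's single-point mutational
    connectivity against label-permutation and path-graph null models.
    Includes an in-package calculator for topological indices on molecular
    graphs (total walk count, Zagreb, Kier kappa, Balaban J, fraction
    descriptors), codon-level mutation combinatorics for the standard genetic
    code, seed-deterministic synthetic-data generators, and regression tools
    for associating chronology scores with proteome amino-acid usage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ape,
    Biostrings,
    optparse
Config/testthat/edition: 3
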