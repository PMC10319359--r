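Package: bgmatch
Title: Bisected Graph Matching for Bilateral Network Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairing of bilaterally homologous nodes in a single directed,
    possibly weighted network that is split into two sides, such as the two
    hemispheres of a connectome. Extends Frank-Wolfe based graph matching
    (the FAQ algorithm) so that the optimization jointly minimizes edge
    disagreements in the ipsilateral (within-side) and contralateral
    (between-side) subgraphs, with support for multiplex edge types, seeded
    (partially known) pairings, and naive padding for sides of unequal size.
    Includes a correlated Erdos-Renyi simulator for bilateral networks,
    accuracy and alignment diagnostics, and scripted simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
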