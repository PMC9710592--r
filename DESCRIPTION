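Package: untangler
Title: Untangling Tanglegrams of Paired Dendrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Data structures and search heuristics for the tanglegram layout
    problem: two dendrograms over the same labelled leaves, drawn face to
    face, are rearranged by subtree rotations so that the straight edges
    joining matching leaves cross as little as possible. Provides the
    linkage-matrix tanglegram model, displacement/entanglement and exact
    crossing counts, the greedy one-sided baseline ('step2side') together
    with three stronger untanglers that rotate both trees simultaneously
    ('stepBothSides') or restart the search from shuffled layouts ('shufS2S'
    and 'ShUnTan'), an exhaustive brute-force oracle for small trees, a
    seeded synthetic tanglegram generator, linkage-table and Newick I/O, a
    benchmark harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
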