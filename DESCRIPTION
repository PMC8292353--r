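Package: complexpaths
Title: Complex Path Length, Bridge Width and Complex Centrality for
    Threshold Contagion on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological measures for the spread of complex contagions, i.e.
    behaviours that require social reinforcement from multiple activated
    neighbours before a node adopts. Provides bridge width between node
    neighbourhoods, the fraction of locally sufficient bridges, complex path
    length and complex centrality, together with a synchronous threshold
    contagion simulator (plus Independent Cascade and Linear Threshold
    robustness models), classical baseline centralities, degree-preserving
    rewired ring lattices and clustering-tunable scale-free graph generators,
    and an experiment harness that relates these measures to cascade outcomes
    on synthetic network ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
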