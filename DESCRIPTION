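Package: resolvti
Title: Resolving Topological Indices and QSPR Models for Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact computation of metric dimension, resolving sets and
    resolving-degree based topological indices (first and second resolving
    Zagreb, resolving hyper-Zagreb and resolving forgotten indices) on
    hydrogen-suppressed molecular graphs, together with the curvilinear
    (linear, quadratic, cubic) and multiple linear regression layer used in
    quantitative structure-property relationship (QSPR) modelling. Ships the
    molecular graphs and physicochemical property data of ten breast-cancer
    drugs as plain-text fixtures, a deterministic generator of random
    molecular-like graphs with synthetic property vectors, and a command-line
    interface that reproduces the full index and regression pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
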