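Package: cogmapsr
Title: Neural-Network Successor Representations for Spatial and Linguistic Cognitive Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for successor-representation (SR)
    cognitive maps. Builds discrete spatial state spaces (an open square room
    and a corridor maze with side arms) and an artificial 40-word language with
    construction-rule syntax; computes exact transition-probability and
    discounted successor-representation matrices; trains a three-layer
    feed-forward softmax network on sampled state-successor pairs to recover
    these matrices, and a small deep Q-learning agent to navigate the maze
    toward reward sites; and analyses the results through eigendecomposition of
    SR matrices into grid-cell-like spatial maps, classical and
    stress-minimizing multidimensional scaling of TP/SR row vectors, and
    cluster-purity diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
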