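Package: leafcoex
Title: Rank-Based Coexpression Analysis of Maize Aquaporins Along the Leaf Developmental Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Expression profiling, rank-based coexpression network construction,
    module partitioning and cross-family association mining for RPKM profiles
    measured over the four ordered zones (basal, transitional, maturing,
    mature) of the developing maize leaf. Ships the published aquaporin
    expression table and gene catalogue as plain-text fixtures, builds
    correlation networks under a Pearson floor (min_cc) and a neighbour-rank
    cap (max_rank), labels connected-component modules by their gradient
    profile, mines aquaporin-transporter "same expression pattern"
    associations, and simulates RPKM matrices with planted anti-correlated
    modules and ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
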