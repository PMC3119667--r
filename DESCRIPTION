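Package: multiortho
Title: Ortholog Group Inference Across Multiple Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies one-to-one ortholog groups shared by several closely
    related genomes. Gene families are built by Markov clustering of an
    all-vs-all sequence similarity graph, partitioned into super ortholog
    groups (at most one gene per genome) by species-tree-guided iterative
    maximum-weight bipartite matching, and projected onto the species tree as
    binary presence/absence trees whose internal nodes are labeled by a
    constrained minimum-flip parsimony criterion. The labeled trees yield
    ortholog groups together with inferred gene birth, duplication and loss
    events. A single-chromosome genome-evolution simulator (duplications,
    births, losses, reversals, Jukes-Cantor substitution) with tracked ground
    truth and an exact-match evaluator make the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
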