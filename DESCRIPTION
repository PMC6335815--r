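Package: aridEvol
Title: Branch-Specific Gene Gain, Selection and Heat-Stress Expression
    Analyses for Cactophilic Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference machinery for comparative genomics and
    transcriptomics of arid adaptation in cactophilic Drosophila
    (repleta group). Classifies genes into orthologues, inparalogues and
    gene births with a three-criterion rule (similarity, synteny,
    symmetric sister grouping), maps orthogroup origins onto a species
    phylogeny, fits silent-site branch lengths from 4-fold degenerate
    sites, computes NG86 Ka/Ks, tabulates per-branch event excesses
    against silent branch lengths, tests the duplication-selection
    association with exact binomial intervals, builds mutually exclusive
    GO-term sets by Louvain clustering with semantic-similarity edge
    weights and runs set-level enrichment, and analyses heat-shock
    expression time courses (TMM normalisation, moderated differential
    expression, fuzzy c-means trajectory clustering). A synthetic-data
    module generates every input with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ape,
    igraph,
    limma,
    edgeR,
    pracma,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    seqinr,
    mclust
Config/testthat/edition: 3
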