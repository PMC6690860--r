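Package: diasem
Title: Diachronic Distributional Semantics from Year-Sliced Co-Occurrence Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how word meanings change over historical time
    from year-stamped 5-gram corpora. Builds year-sliced word co-occurrence
    matrices, derives word embeddings per year by positive pointwise mutual
    information (PPMI) weighting followed by truncated singular value
    decomposition, aligns embedding spaces across years with orthogonal
    Procrustes rotations, and computes semantic stability scores, 2-D semantic
    drift trajectories, synonym and context networks with Louvain community
    labels, diachronic co-occurrence change tables, and contextual affect
    (valence, arousal, concreteness) time series from published word norms.
    Includes a synthetic-corpus generator with a ground-truth manifest so the
    whole pipeline can be exercised and validated without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    data.table,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
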