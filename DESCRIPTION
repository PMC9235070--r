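Package: scheter
Title: Quantifying Intra-Tumoral Transcriptomic Heterogeneity in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify intra-tumoral transcriptomic heterogeneity in
    single-cell RNA-seq data with two silhouette- and correlation-based
    statistics (the average negative-silhouette-value fraction and the p_diff
    deviation score), to build gene-cluster hierarchies from consensus k-means
    clustering over a range of cluster numbers, to reduce those hierarchies by
    collapsing stumps, to determine uniquely enriched gene sets along hierarchy
    paths, to align hierarchies from multiple datasets into meta gene clusters
    via non-negative matrix factorization of path-subgraph edge memberships,
    and to validate cluster signatures in bulk expression and survival data.
    Includes simulators for tumor-mixture toy data, multi-dataset hierarchies
    with planted shared structure, and bulk expression with survival signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
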