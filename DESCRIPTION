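Package: conCluster
Title: Consensus Clustering of Single-Cell RNA-Seq Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cell subpopulations from single-cell RNA-seq
    expression matrices by consensus clustering. The pipeline filters rare,
    ubiquitous and low-variability genes, embeds cells in two dimensions
    with t-SNE, generates an ensemble of K-means basic partitions encoded
    as one-hot membership matrices, fuses the concatenated ensemble with
    K-means into a consensus partition, selects the number of clusters with
    the Calinski-Harabasz index, and evaluates agreement between partitions
    with the Adjusted Rand Index. Includes a negative-binomial synthetic
    data generator with mean-dependent dropout so the full pipeline can be
    exercised without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    Rtsne,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
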