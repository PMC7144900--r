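Package: hictad
Title: Hierarchical Topologically Associating Domain Calling from Hi-C
    Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies the full hierarchy of topologically associating
    domains (TADs) in dense intra-chromosomal Hi-C interaction matrices.
    The caller denoises the input map through a Pearson-correlation
    transform followed by principal component analysis, partitions the
    region with constrained incremental sum-of-squares (CONISS)
    hierarchical clustering, bounds the number of significant hierarchy
    levels with the broken-stick model, and selects the optimal level and
    number of retained components with the Calinski-Harabasz index.
    Companion tools quantify agreement between genome partitions (Measure
    of Concordance, border overlap score with permutation p-values),
    localize topological differences between two partitions (DiffT score
    with per-bin permutation significance), and measure ChIP-seq
    peak/signal enrichment at domain boundaries and bodies. A synthetic
    generator produces nested block-structured contact matrices with known
    ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
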