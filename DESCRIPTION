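Package: bootbin
Title: Bootstrapped Supervised Binning of Metagenomic Contigs and Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-independent deconvolution of metagenomic assemblies or
    long sequencing reads into population-level genomic bins. Sequences are
    represented by canonical oligonucleotide (pentamer) frequency signatures,
    size-selected into cluster, border and remaining points, optionally
    compressed by random sampling of representative points, embedded in 2D by
    Barnes-Hut t-SNE, clustered density-based (DBSCAN) on the cluster points
    only, and finally assigned to bins by a random-forest classifier trained
    on the de novo cluster labels. Includes fixed-length chunking of long
    contigs for cluster-density normalization, ground-truth evaluation
    (per-genome sensitivity, precision, F1), a synthetic-community simulator,
    and a static HTML/JSON report with convex hulls per cluster.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rtsne,
    randomForest,
    FNN,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
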