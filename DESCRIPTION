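Package: chromint
Title: Sequence-Based Prediction of Plant Chromatin Interactions with a
    CNN + Transformer Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts chromatin interactions between pairs of plant genomic
    sequences (promoter-promoter and promoter-distal element pairs) from DNA
    sequence alone, using a convolutional + multi-head self-attention
    classifier trained end-to-end with backpropagation implemented in base R.
    Includes sequence extraction and one-hot encoding conventions for
    promoter and distal-element anchors, a synthetic planted-motif data
    generator for benchmarking, genome tiling and region-scan utilities that
    build interaction maps and rank candidate target genes, and an
    interpretability suite: integrated-gradients attribution, continuous-run
    motif calling, motif cooperation scanning, in-silico saturation
    mutagenesis, and permutation-based interval enrichment with two control
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
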