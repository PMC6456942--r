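Package: epideep
Title: Multi-Marker Histone Modification Site Prediction from Sequence and Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts histone modification sites for seven histone markers
    simultaneously by integrating DNA sequence and DNase-seq chromatin
    accessibility through a dual-branch densely connected convolutional
    network trained with multi-label binary cross entropy. Includes the full
    dataset-construction rules (200-bp genome scanning, 100-bp overlap site
    calling, one-vs-rest labels, per-base openness encoding), 5-fold
    cross-validation with auROC/auPRC evaluation and exact paired sign tests,
    cross-epigenome collective scoring, convolutional-kernel motif extraction
    with MEME export, in-silico variant effect scoring for haQTL-style
    analyses, and a synthetic fixture generator with planted motifs so the
    whole pipeline is exercisable end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
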