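Package: framepoolr
Title: Frame-Aware Pooling Models for Mean Ribosome Load Prediction from
    5'UTR Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts mean ribosome load (MRL) from 5' untranslated region
    (5'UTR) sequences of any length using convolutional models with
    frame pooling: global max and average pooling applied separately
    within each of the three reading-frame position classes, anchored at
    the canonical start codon. Includes the full training protocol
    (Adam, mean-squared-error loss, early stopping, two-library scaled
    training), frame-unaware convolutional and k-mer random-forest
    baselines, a leaky-scanning simulator that generates MPRA-like
    sequence/MRL datasets with frame-dependent upstream initiation
    effects, a VCF/BED/FASTA variant-effect pipeline reporting log2 MRL
    fold changes and simulated-frameshift scores, upstream translation
    initiation site strength scoring, gradient-based contribution
    scores, saturation mutagenesis, and bootstrap model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    optparse,
    ranger,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
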