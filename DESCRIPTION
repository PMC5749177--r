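Package: pwmnet
Title: PWM-Anchored Convolutional Networks for Cross-Cell-Type Chromatin
    Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts a seven-category cross-cell-type chromatin accessibility
    label for 500-bp DNA windows with a four-layer convolutional network whose
    first layer is frozen to log-transformed transcription-factor position
    weight matrices. Includes DeepLIFT (Rescale) attribution of predictions to
    individual TF filters, per-locus key-TF assignment, in-silico saturation
    mutagenesis, haplotype-partitioned prediction of chromatin accessibility
    QTL allelic effects, a per-individual inter-individual variability
    statistic, and a fully seeded synthetic-data generator (motif-planted
    sequences, phased haplotype panels, simulated allelic imbalance) so that
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
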