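Package: chromcast
Title: Cell-Type-Generalising Histone Mark Prediction from DNA and Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting histone-mark signal tracks in previously
    unseen cell types from DNA sequence plus chromatin accessibility.
    Implements signal-track input/output and rebinning, training-window
    selection with coverage filtering and mark balancing, per-window target
    construction (cross-cell average, signal distribution and cell-minus-average
    delta), a dual-branch model with a frozen pluggable DNA backbone and a
    cell-typing branch embedding local and global accessibility, two-stage
    training with frozen-backbone latent caching, full-receptive-field in
    silico mutagenesis variant scoring with histone-QTL summary-statistic
    munging and aggregation, receptive-field and off-centre probing with
    gradient attribution, evaluation protocols, and a synthetic-data generator
    with a planted regulatory grammar for end-to-end testing at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse,
    pROC,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
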