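Package: psspkit
Title: Protein Secondary Structure Prediction with a Targeted Autoencoder
    and Multi-Task Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for protein secondary structure
    prediction (PSSP). Implements per-residue feature encoders (one-hot,
    physicochemical, PSI-BLAST PSSM and HH-suite HMM profile readers,
    pluggable language-model embeddings), the segment-overlap (SOV) and
    Q accuracy evaluation metrics with boundary-residue analysis,
    contingency-table association analysis between secondary structure
    and relative solvent accessibility (Cramer's V), a calibrated
    synthetic corpus generator, and two trainable neural models written
    from first principles: a highly targeted autoencoder (dynamic
    one-dimensional convolution encoder with a BiLSTM decoder trained by
    masking single-category structure segments) and a multi-task
    predictor combining multi-scale residual convolution, multi-gate
    mixture-of-experts parameter sharing, and temporal convolution with
    BiGRU towers for joint 3-/8-state structure and solvent-accessibility
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
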