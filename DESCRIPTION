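Package: convmotif
Title: Motif Discovery from Single-Layer Convolutional Sequence Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene expression status from transcription start site
    centered promoter windows with a single-convolutional-layer neural
    network and interprets the trained first-layer kernels as sequence
    motifs. The central step is an N-adjusted kernel transformation that
    uses the cryptic-nucleotide (N) channel weight as a per-position bias
    control when converting each kernel into a position weight matrix.
    Includes a synthetic planted-motif benchmark generator, FPKM-threshold
    expression labelling, window extraction and one-hot encoding, DeepLIFT
    style rescale attribution, MEME minimal motif format input/output,
    PWM similarity and common-motif calling across cross-validation folds,
    forward-strand log-odds scanning with exact p-values, and an SVM
    validation harness on motif-count features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
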