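Package: rhizoseg
Title: Attention U-Net Segmentation and Length Quantification of Fine Roots
    in Rhizotron Imagery
Version: 0.1.0
Authors@R:
    person("R.", "Holt", email = "rhizoseg@posteo.net", role = c("aut", "cre"))
Description: Tools for segmenting fine roots in field rhizotron and
    minirhizotron imagery with an improved U-Net: a convolutional block
    attention module (CBAM) after every double-convolution block, an
    additive attention-modulated decoder fusion (UpAdd), and a hybrid
    Dice/focal/edge loss.  Includes sliding-window patch extraction with
    7:2:1 splitting, HSV preprocessing and stochastic augmentation, a pure-R
    training loop (AdamW, cosine annealing) with transfer-learning
    fine-tuning, confusion-matrix evaluation with a validation threshold
    sweep, skeleton-based root-length extraction, Pearson agreement
    statistics with Bonferroni correction, and a synthetic rhizotron image
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    png,
    jpeg,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
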