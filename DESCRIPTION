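Package: mtpi
Title: Transfer-Point and Sample-Size Selection for Segmentation Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for planning transfer learning of semantic-segmentation
    networks before any trial-and-error fine-tuning. Implements the Maximum
    Transfer Potential Index (MTPI) procedure: per-layer feature probing of a
    pre-trained network on a shifted target domain, a transfer potential index
    balancing accuracy potential (weighted Cohen kappa of layer-feature
    mappings) against retraining cost (trainable-parameter level), selection
    of the freezing depth TP0 and of the transfer dataset size TDS0, and
    execution and evaluation of the transfer. Ships a seedable synthetic
    4-class vegetation scene simulator with a parametric season-like domain
    shift, a palette label codec with joint image/label augmentation, weighted
    segmentation metrics (pixel accuracy, recall, F1, IoU, Cohen kappa), and a
    small trainable encoder segmentation network with enumerable transfer
    points and exact frozen-parameter accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png,
    generics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
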