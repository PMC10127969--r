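Package: mbsnet
Title: Multi-Branch Segmentation Networks for Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements MBSNet, a light multi-branch encoder-decoder network for
    binary medical-image segmentation, together with the machinery needed to train
    and evaluate it on CPU: a small reverse-mode differentiation engine with
    Rcpp/Armadillo convolution kernels, the parallel residual mixer (PRM),
    multi-grid dilated convolution blocks, squeeze-and-excitation and spatial
    attention modules, feature cross-fusion decoding, the joint Dice and binary
    cross-entropy loss, IOU/F1/G-mean evaluation metrics, TOPSIS multi-criteria
    model ranking, a synthetic lesion image generator for desk-scale experiments,
    and parameter/MAC complexity accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
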