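Package: scintiseg
Title: Adversarial Multi-Scale Segmentation of Bone Scintigrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for segmenting metastatic bone lesions in planar
    nuclear-medicine bone scintigrams (16-bit radiotracer count images).
    Implements a conditional adversarial segmentation framework in which an
    encoder-decoder generator built from cascade dilated convolutions,
    multi-scale feature-extraction blocks and residual multi-scale decoder
    blocks, with image-pyramid inputs and deep supervision, is trained
    against a multi-layer convolutional critic via a multi-scale L1 loss on
    image-mask products. Includes receptive-field arithmetic for dilated
    convolution stacks, a synthetic scintigram phantom generator with
    Poisson count noise, patient-grouped dataset splitting, Dice-based
    objectives, evaluation metrics, and a command-line interface. All
    network layers (convolution, batch normalisation, pooling, bilinear
    interpolation) and their gradients are implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
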