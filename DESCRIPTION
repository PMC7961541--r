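Package: coralseg
Title: Semantic Segmentation of Single-Channel Coral Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pixel-level segmentation of coral versus background in
    single-channel underwater images. Implements an encoder-decoder
    convolutional network with a pruned ResNet34 backbone, atrous spatial
    pyramid pooling, space-to-depth/depth-to-space resampling and a large-kernel
    fusion decoder, together with image-level backbone pre-training, a class
    activation mapping head for weak localization, a segmentation metric suite
    (precision, recall, F1, mean IoU), a synthetic coral-scene generator for
    desk-scale experiments, and a command-line interface. The numerical core
    (convolution, batch normalization, pooling, resampling and their gradients)
    is implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
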