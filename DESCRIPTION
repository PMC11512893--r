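Package: spinalzfnet
Title: Hybrid SpinalNet-ZFNet Classification of Kidney CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for four-class kidney disease
    classification (normal, cyst, tumor, stone) from 2-D grayscale CT
    slices: median-filter denoising, ENet encoder-decoder kidney
    segmentation, geometric augmentation, a four-branch handcrafted
    feature bank (SURF interest-point descriptors, Weber local
    descriptor on Haar wavelet subbands with histograms of oriented
    gradients, region shape features, and gray-level co-occurrence
    statistics), and a hybrid SpinalNet/ZFNet classifier joined by a
    gated fusion layer.  Includes a seeded synthetic CT phantom
    generator, a reverse-mode automatic-differentiation engine with
    compiled convolution kernels for training the networks on a CPU,
    K-fold and learning-set evaluation protocols with multiclass ROC
    analysis, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
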