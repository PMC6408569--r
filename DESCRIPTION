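Package: cohsr
Title: Super-Resolution for Coherent Holographic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for resolution enhancement of coherent (holographic) imaging
    systems. Implements the classical reconstruction chain of lensfree on-chip
    and lens-based in-line holographic microscopes (angular-spectrum free-space
    propagation, edge-sparsity autofocusing, SVD background subtraction,
    iterative multi-height phase recovery, shift-and-add pixel super-resolution,
    and correlation-based image registration), a generative adversarial network
    for learned super-resolution of complex-valued images (U-Net generator,
    convolutional discriminator, composite L1, total-variation, adversarial and
    SSIM losses, trained with Adam at a 4:1 generator:discriminator update
    ratio), evaluation metrics (structural similarity, radially averaged
    spatial-frequency spectra), and a seeded synthetic-data generator that
    emulates tissue-like complex objects, multi-height hologram stacks,
    sub-pixel shifted low-resolution acquisitions, fixed-pattern backgrounds
    and shot noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
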