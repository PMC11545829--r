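Package: lungscreen
Title: Lightweight Lung-CT Nodule Detection and Risk Screening Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-testable lung computed-tomography early-detection
    pipeline: Ricker-wavelet iterative center-weighted-median denoising
    (RWICWM), Sorensen-Dice-index K-means segmentation, Weibull-distributed
    scale-factor Light Spectrum Optimizer (WDSI-LSO) multilevel-threshold
    nodule candidate detection with shape-feature filtering, PLCOm2012-style
    logistic risk stratification, and a small semi-supervised contrastive
    classifier. Ships a seeded synthetic chest-phantom generator with ground
    truth so every stage is testable without clinical data, plus image-quality
    (PSNR, MSE, SSIM) and confusion-matrix metrics and an end-to-end pipeline
    runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
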