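Package: stlbp
Title: Spatio-Temporal Local Binary Pattern Descriptors for Subtle-Motion Video Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and evaluation toolkit for dynamic-texture
    analysis of grayscale video, aimed at subtle facial micro-movement
    recognition. Implements the basic local binary pattern (LBP) operator with
    circular neighborhoods and block-wise histograms, its spatio-temporal
    extension on three orthogonal planes (LBP-TOP), and two compact variants:
    LBP-SIP, which codes only the six intersection points of the orthogonal
    planes as a 16+4 bin histogram per block, and LBP-MOP, which codes the
    three mean plane images of a video volume. Includes adaptive Wiener
    denoising, Gaussian pyramid construction, linear temporal resampling,
    a seeded synthetic video-corpus generator, and an SVM cross-validation
    harness with leave-one-video-out and leave-one-subject-out protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    png,
    tiff,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
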