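Package: gazemetrics
Title: Quantitative Comparison of Human Gaze Attention and Classifier Saliency Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing human eye-gaze attention maps with
    occlusion-based classifier saliency maps over facial images of genetic
    conditions. Provides fixation-to-map rendering with a truncated Gaussian
    kernel, common-attention subtraction, box-filter smoothing, noise and
    coverage thresholding, occlusion saliency for any classifier satisfying a
    probability-vector contract, IoU and symmetric Kullback-Leibler map
    comparison with participant-level bootstrap standard deviations,
    DerSimonian-Laird random-effects pooling across images, area-of-interest
    fixation metrics, and a synthetic-cohort generator with known ground truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
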