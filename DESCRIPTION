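Package: thromboquant
Title: Morphological Classification and Quantification of Platelet Thrombi in
    Flow-Chamber Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage machine-learning quantification of fluorescence
    flow-chamber images of platelet aggregates. A pixel classifier separates
    platelet-covered area from background from a multi-scale filter-bank
    feature stack; an object classifier assigns each connected structure a
    probability of being a compacted thrombus (bright rim, dark core), rendered
    as an 8-bit probability map and thresholded before morphometry. Includes
    rolling-ball background subtraction, particle morphometry (area, Feret
    diameter, hole filling), segmentation evaluation (Jaccard index,
    threshold-swept ROC from per-image confusion matrices), paired and
    repeated-measures statistics, a synthetic-scene generator with ground
    truth for benchmarking, and an end-to-end headless workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    xgboost,
    ranger,
    withr,
    rlang,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
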