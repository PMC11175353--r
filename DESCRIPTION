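Package: casatrack
Title: Small-Object Detection Losses, Tracking-by-Detection, and Evaluation
    for Computer-Assisted Sperm Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a detection-and-tracking pipeline for
    human sperm in microscopy video. Implements a family of bounding-box
    similarity measures and regression losses for tiny objects (IoU, CIoU,
    MPDIoU, Inner-IoU, and the Normalized Wasserstein Distance, with their
    weighted combination), the architectural operators of a small-object
    detector (space-to-depth convolution, multi-scale convolutional
    attention, efficient multi-scale attention, a dynamic detection head,
    and an extra high-resolution detection level) together with exact
    parameter accounting of the detector graph, a tracking-by-detection
    multi-object tracker with Kalman filtering, Hungarian assignment,
    blended motion/appearance association and observation-centric recovery,
    a full detection and tracking evaluation suite (precision, recall, mAP,
    MOTA, MOTP, IDF1, HOTA), and a synthetic microscopy simulator that
    emulates the statistics of wet-preparation semen video so the whole
    pipeline is testable end to end without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml
Config/testthat/edition: 3
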