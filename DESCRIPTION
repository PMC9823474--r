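Package: eyeframeqc
Title: Quality Control of Pupillometer Eye Frames
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Frame-level quality control for infrared pupillometry video.
    Implements a deterministic six-class frame-labeling rule engine based on
    pupil position and eyelid occlusion, a rule-based (expert-system) pupil
    detector built from thresholding, anisotropic smoothing, adaptive
    binarization, morphology and convex-hull contour scoring, a classical
    machine-learning benchmark (unrolled pixels, histogram-of-oriented-
    gradients and local-binary-pattern features across several classifiers),
    and a latency-aware figure of merit combining classification accuracy
    with single-frame prediction time. A built-in synthetic eye-frame
    generator renders labeled device-like frames (lens disc, iris, dark
    pupil, glint ring, eyelid occlusion, sensor noise) with exact ground
    truth, so the whole stack can be exercised and validated without access
    to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    rpart,
    nnet,
    class,
    MASS,
    Matrix,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
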