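Package: pestyolo
Title: Light-Trap Pest Detection with an Attention-Augmented YOLO Detector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of a lightweight one-stage
    detector for multi-class insect monitoring in light-trap images. The
    package provides a coordinate-and-local attention (CLA) operator, a
    grouped spatial-pyramid-pooling cascade (GSPPF), the full anchored
    three-scale detector with GIoU regression loss and YOLO-style online
    augmentations, Gaussian Soft-NMS post-processing, AP/mAP evaluation
    with a noise-robustness harness, and a seeded synthetic light-trap
    scene generator so the whole stack is testable without external data.
    All network operators run on a small built-in reverse-mode autodiff
    engine over base-R arrays, so models can be trained and profiled on
    CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
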