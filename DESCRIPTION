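Package: fallmon
Title: Silhouette-Kinematic Human Fall Detection from Surveillance Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A camera-based human fall detection pipeline built on silhouette
    kinematics. Video frames are background-subtracted to 1-bit silhouette
    masks from which apparent height, width, tilt angle, normalized velocity
    and acceleration are extracted; humans are located by a sliding-window
    histogram-of-oriented-gradients detector scored by a sparse Bayesian
    relevance vector machine, associated across frames by a Viterbi dynamic
    program, and candidate clips are classified as falls by a PCA-compressed
    clip classifier followed by a crafted post-hoc rule engine (electronic
    fence, visibility, steep-angle height ratios, inactive time). Includes a
    deterministic synthetic fall-scene generator producing labeled clips of
    falls and daily activities with ground truth, so every stage is testable
    without external video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
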