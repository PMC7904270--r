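Package: gazetrackr
Title: Single-Camera Gaze Tracking Under Natural Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A feature-based gaze-tracking toolkit for single-camera,
    natural-light recordings. Locates iris centers in low-resolution eye
    regions with an anatomically initialized snakuscule (a circular
    disk/annulus contrast probe), derives eye vectors from a stable facial
    anchor point averaged over 36 rigid landmarks, estimates head pose from
    six 2D-3D landmark correspondences, and maps eye vectors plus head pose
    to on-screen points of regard with second-order polynomial regression
    and weighted binocular fusion. Ships synthetic eye-image and
    gaze-session generators so the whole pipeline is testable without any
    recorded data, plus the standard evaluation metrics: the normalized
    iris-center error and horizontal/vertical/combined angular gaze errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
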