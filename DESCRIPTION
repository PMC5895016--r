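Package: vitalmag
Title: Eulerian and Phase-Based Video Magnification for Remote Vital-Sign
    Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reveals sub-pixel periodic motion, such as the chest movement of
    a breathing person, in ordinary video. Implements two magnification
    pipelines: intensity-based Eulerian linear video magnification built on
    Laplacian pyramids with temporal Butterworth bandpass filtering, and
    phase-based magnification built on the complex steerable pyramid, where
    local phase differences are temporally filtered and amplified. Includes
    PSNR/MSE quality metrics, a sub-pixel phase-correlation displacement
    oracle, respiration-rate estimation from motion traces, and a synthetic
    ground-truthed scene generator for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
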