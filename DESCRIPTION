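Package: handrep
Title: Type and Intensity Assessment of Repetitive Hand Movements from
    Video-Derived Skeletal Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring repetitive hand movements (clapping,
    picking, rubbing, scratching, hand wringing) from 2-D body and hand
    keypoint sequences extracted from video. Recordings in the OpenPose
    per-frame dialect are imputed, resampled to 30 frames per second,
    scale-normalised to shoulder-width units, smoothed with a
    Savitzky-Golay filter, reflected so the dominant hand is on the
    right, and cut into analysis windows. Each window is summarised by
    discriminative poses (mean pose plus the poses where the hand
    centroids are furthest apart and closest together) and classified
    with a Naive Bayes Nearest Neighbour rule. Movement intensity
    (repetitions per window) is counted by prominence-filtered peak
    detection on normalised inter-hand distance signals, with
    class-specific hyperparameters tuned by grid search, and scored
    against global range boundaries or personalised per-subject
    boundaries. A parametric generator produces synthetic keypoint
    recordings of the five movement archetypes with ground-truth
    repetition rates for testing and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
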