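Package: kinerehab
Title: Kinematic Analysis, Exercise Recognition and Real-Time Feedback from
    Body Keypoint Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns 33-landmark body-keypoint video traces (BlazePose
    topology) into kinematic assessments for home-based tele-exercise:
    joint angles and range of motion against normative values, angular
    velocity, movement coordination by cross-correlation, and per-exercise
    execution-error checks. Includes motion/pause detection, singular
    spectrum analysis detrending, repetition segmentation, per-repetition
    time/frequency feature extraction with PCA and classical classifiers
    (random forest, support vector machines, decision tree) for
    recognizing five rehabilitation exercises, a real-time feedback
    session engine, and a parametric synthetic skeleton-motion generator
    that makes the whole pipeline testable without video recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
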