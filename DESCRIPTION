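Package: gaitprint
Title: Gait Recognition by Histogram Intersection on Mobile Motion Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Treats a person's manner of walking as a behavioural biometric
    measured by the tri-axial accelerometer and gyroscope of a smartphone.
    Fixed-duration sensor windows are converted to per-axis directional
    histograms through an arcsine transform, compared by histogram
    intersection, and fused across sensors to classify users, verify a
    claimed identity against an enrolment-derived threshold, and cluster
    samples by device placement with k-medoids over a similarity-derived
    distance. Includes readers for segment-file and timestamped-recording
    layouts, a seeded synthetic gait generator for end-to-end testing
    without recorded data, a continuous-authentication session policy
    driven by activity events, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    withr,
    generics,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster
Config/testthat/edition: 3
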