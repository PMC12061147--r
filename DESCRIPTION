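Package: imupunch
Title: Boxing Punch Detection and Classification from Wrist IMU Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies boxing punches (jab, hook, uppercut, per
    hand) from 6-DoF wrist-worn inertial measurement unit streams. Slides
    fixed-length windows over accelerometer/gyroscope signals, extracts
    time-domain and Welch spectral features, labels windows against video
    ground truth by a percentage-overlap criterion, and trains a
    naive-Bayes / decision-tree / k-nearest-neighbour committee with a
    pool-based query-by-committee active-learning loop that needs only a
    small fraction of windows labeled. Detected per-window labels are
    smoothed under minimum-gap and minimum-duration constraints and turned
    into punch events with start/end times, per-type counts, and
    frame-accurate video cut lists via UTC clock synchronization. Includes
    a synthetic-session generator with ground-truth annotations for
    end-to-end testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rpart,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
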