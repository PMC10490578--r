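Package: emgdtw
Title: Distance-Based Gesture Classification for Multichannel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of hand gestures from multichannel surface
    electromyography (sEMG) recordings by length-normalized dynamic time
    warping (DTW) and 1-nearest-neighbor matching. Provides a restricted-step
    DTW with warping-path extraction and an exhaustive-enumeration test
    oracle, cluster condensing by representative selection or DTW barycenter
    averaging (DBA), intra- and intercluster distance distributions with
    percentile-based separability reports and gesture-subset selection,
    distance-cutoff acceptance metrics (total accuracy, classification
    accuracy, rejection rate) with percentile-cutoff sweeps, maximum-
    voluntary-contraction normalization across participants, and a synthetic
    sEMG generator emulating multi-seating armband datasets so the full
    pipeline runs without access to private recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
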