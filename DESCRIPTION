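Package: seizr
Title: EEG Seizure Classification with Random Data Augmentation, Fuzzy
    Features and Swarm-Tuned LSTM Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Maintainer [aut, cre]
Maintainer: Package Maintainer <maintainer@example.org>
Description: Tools for binary classification of epileptic versus
    non-epileptic single-channel EEG segments. Reads Bonn-format ASCII
    segments and generates synthetic look-alike datasets; preprocesses
    signals with zero-phase Butterworth band-pass filtering, running-median
    smoothing and a rational-dilation wavelet transform with perfect
    reconstruction; enlarges scarce seizure data with label-preserving
    random augmentation (amplitude scaling, circular time shift, width
    warping); extracts windowed statistical features refined by fuzzy
    C-means clustering; tunes a long short-term memory classifier with
    particle swarm optimization or a parrot optimizer with Levy-flight
    steps; and reports nine confusion-matrix metrics including Matthews
    correlation, Cohen's kappa, critical success index and the
    Fowlkes-Mallows index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
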