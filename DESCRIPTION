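Package: hsiband
Title: Standard-Deviation-Based Spectral Band Selection for Hyperspectral
    Microscopy Hypercubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ranking-based spectral band selection in hyperspectral
    microscopy. Scores every spectral channel of a hypercube by spatial
    standard deviation, mutual information with the per-pixel mean spectrum,
    or Shannon entropy, and selects the contiguous sliding window that
    maximizes the cumulative score, with a uniformly random window as the
    chance baseline. Includes a hypercube data model with ENVI and
    single-file container input/output, a synthetic tissue-like hypercube
    simulator with a planted informative wavelength window, a compact
    convolutional neural network training and evaluation harness for
    whole-cube classification, and a reproducible experiment pipeline
    comparing the selection criteria over repeated seeded runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
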