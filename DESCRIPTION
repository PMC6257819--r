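Package: oscdecode
Title: Decoding Hierarchical Serial-Order Control Codes from Oscillatory EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for tracking hierarchical
    serial-order control representations (sequence elements, within-chunk
    positions, chunk identities, chunk positions) in rhythmic EEG activity.
    Provides a cycling-sequence task generator with full counterbalancing,
    a synthetic multichannel EEG generator with 1/f background noise and
    band-limited oscillatory codes, Morlet wavelet time-frequency
    decomposition, frequency-by-time multivariate decoding with
    shrinkage-regularized linear discriminants and repeated cross-validation,
    cluster-based permutation inference, cross-condition generalization,
    representational similarity analysis of confusion matrices, an
    associative-chaining asymmetry test, and single-trial brain-behavior
    mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
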