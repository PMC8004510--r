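Package: eegstream
Title: Real-Time Source Reconstruction of High-Density EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration-based spatial filtering for online analysis of
    high-density electroencephalography (EEG). Builds a three-shell
    spherical head model and analytic leadfield, estimates bad-channel
    repair, average-reference, ICA-derived artifact-attenuation and
    eLORETA/MNE/sLORETA source-localization filters from a calibration
    recording, applies them per buffer to a replayed or live sensor
    stream, and validates the reconstructions with event-related
    desynchronization (ERD) mapping. Includes a ground-truth simulator
    of task-modulated dipolar sources with ocular and muscle artifacts,
    plus readers for SFP/ELC electrode files and EDF/BrainVision
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
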