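Package: ecgage
Title: Neural-Network Age Estimation from 12-Lead ECGs: Acquisition,
    Augmentation, Corruption and Transfer Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying deep-learning estimation of age from 10-second
    twelve-lead electrocardiograms. Provides two fully specified
    one-dimensional convolutional architectures (an eight-block
    temporal/spatial network and a four-block residual network) with an
    analytic complexity accountant (parameters, multiply-adds, serialized
    size), a synthetic annotated ECG cohort generator whose beat morphology
    encodes age, WFDB-format input/output, acquisition-parameter
    preprocessing (sampling-rate interpolation, duration truncation, stretch
    upsampling, pad-to-grid), batch augmentation (baseline flip, time
    reversal, random crop) and fiducial-interval corruption schemes, plus a
    cross-validated training, fine-tuning and transfer harness that runs on
    a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
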