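Package: psgpheno
Title: EEG/EMG Phenotyping of Mouse Polysomnography Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for chronic mouse EEG/EMG (polysomnography)
    phenotyping: Welch power spectral density estimation with seven-band
    segmentation and a low/high-frequency power-ratio biomarker
    ((alpha+beta1+beta2)/gamma2), poly-spike episode detection, sleep
    architecture quantification with scorer-agreement metrics, and
    association fits of phenotypes against molecular covariates
    (one-phase exponential decay and linear regression). Includes a
    synthetic polysomnography generator with graded genotype and protein
    covariates, and minimal European Data Format (EDF) input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
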