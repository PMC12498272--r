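Package: asapms
Title: ASAP-MS Plasma Fingerprint Processing and Clinical Outcome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and machine-learning analysis of atmospheric solids
    analysis probe mass spectrometry (ASAP-MS) molecular fingerprints of blood
    plasma. Converts raw time-ordered scan streams into background-corrected,
    unit-mass-binned, area-normalised spectra; builds balanced and
    extreme-patient binary classification cohorts from clinical variables;
    applies three feature-reduction methods (point-biserial correlation,
    distribution overlap integrals, and chi-squared feature ranking); evaluates
    five classifier families over repeated stratified 80:20 holdouts scored by
    accuracy and Cohen's kappa; and identifies consensus discriminative m/z
    peaks selected across methods and partitions. Includes a synthetic-cohort
    generator with planted class effects so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    MASS,
    class,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
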