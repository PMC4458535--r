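Package: adstager
Title: Staging of Alzheimer's Disease from Volumetric and
    Neuropsychological Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pairwise staging of Alzheimer's disease and its prodromal
    stages (CN, EMCI, LMCI, AD) from regional brain volumes and
    neuropsychological scores. Implements stepwise linear regression
    feature extraction driven by R-squared increment thresholds,
    resampling-consensus stabilization of the selected feature set,
    a two-class linear discriminant classifier with posterior
    probabilities, cross-validated incremental-feature evaluation, and
    a neuropsychological/MRI/combined model comparison. Includes a
    synthetic four-group cohort simulator with planted atrophy effects
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
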