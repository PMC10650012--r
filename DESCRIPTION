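Package: sipemg
Title: Swallow Event Detection and Fluid-Intake Volume Estimation from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting fluid-swallowing events and estimating per-sip
    fluid volume from two-channel surface electromyography (sEMG) of the
    infrahyoid muscles. Provides a seeded synthetic study generator emulating a
    multi-subject, multi-day drinking protocol; zero-phase band-pass filtering,
    rectified-envelope computation and peak-centred burst segmentation; a
    catalogue of twenty-six time- and frequency-domain burst features;
    cross-validated classification (F-score) and sip-volume regression (RMSE)
    with exhaustive feature-subset search, global versus subject-specific
    feature selection, and cross-day transfer evaluation; and a configurable
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    randomForest,
    rpart,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
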