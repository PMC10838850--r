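Package: sinusmie
Title: Maxillary Sinus Anomaly Classification by Centroid Sampling and
    Multiple Instance Ensembling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for classifying paranasal anomalies
    (polyps and cysts) of the maxillary sinus in registered 3D head-and-neck
    MRI. Sinus volumes are localized without learning by sampling candidate
    centroids from per-axis Gaussian (or equidistant) distributions, cropped
    as overlapping cubic patches, flipped to a common left-sinus orientation,
    and resampled to a fixed 64x64x64 classifier input. A compact 3D
    convolutional network scores each instance and Multiple Instance
    Ensembling averages the softmax probabilities over all instances of a
    sinus. Includes a synthetic phantom-cohort generator, patient-level
    stratified cross-validation, AUPRC/F1 evaluation for imbalanced labels,
    and report helpers for sampling-strategy and architecture comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
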