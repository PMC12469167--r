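Package: mngsort
Title: Supervised Spike-Sorting Feasibility for Microneurography C-Fibre Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess whether noisy single-electrode microneurography
    recordings of human C-fibres can be sorted reliably. Recordings labelled by
    the marking method (low-frequency background electrical stimulation that
    time-locks one spike per fibre per stimulus) are harmonized into a common
    data model; spike windows are extracted, resampled, differentiated and
    aligned at the negative peak of the first derivative; six waveform feature
    sets (amplitude/width, shape-phase-distribution features and a reduced
    three-feature subset, the raw waveform, and 2/3-component PCA scores) are
    computed; per-recording sortability is estimated by cross-validated SVM or
    random-forest classification, k-means clustering scored against the track
    labels (ARI, NMI, V-measure), and between-template distances (MSE/MAE/RMSE).
    A parametric generator of marking-method recordings with activity-dependent
    slowing provides ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
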