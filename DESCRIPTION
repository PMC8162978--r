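Package: scavote
Title: Selective Class Average Voting Ensembles for Imbalanced Radiogenomic Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble voting for imbalanced binary classification of tumor
    mutation status from radiomic features, centered on Selective Class
    Average Voting (SCAV): models voting for the rare (mutant) class are
    counted against a tuned threshold and pseudo-probabilities are averaged
    only over the models on the winning side. Includes average and maximum
    voting baselines, member selection by training AUC, Mann-Whitney and
    ReliefF feature ranking, SMOTE minority oversampling, a leakage-free
    stratified cross-validation pipeline with pluggable classifier adapters,
    radiomic feature extraction (histogram, grey-level size-zone and
    run-length texture, 3D Laws and Haar wavelet energies, shape) from
    segmented tumor volumes, tumor ROI slice selection, patient-grouped
    splits, and synthetic data generators emulating imbalanced radiogenomic
    cohorts so the whole pipeline is testable without protected image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    e1071,
    nnet,
    igraph,
    withr
Config/testthat/edition: 3
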