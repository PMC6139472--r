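Package: fcmvpa
Title: Task-Dependent Functional Connectivity Multivariate Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for classifying subject groups from task-dependent
    functional connectivity patterns in event-related fMRI. Builds cube-shaped
    nodes from stereotaxic coordinates (with Talairach/MNI conversion),
    extracts voxel-wise BOLD time-series, computes psychophysiological
    interaction (PPI) node time-series via regularized hemodynamic
    deconvolution, assembles lower-triangle Pearson connectivity features, and
    runs incremental-feature linear SVM classification under leave-one-out
    cross-validation with a label-permutation null. A synthetic-data module
    generates two-group cohorts of 4D BOLD runs with known condition-dependent
    inter-node coupling so every stage can be verified against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
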