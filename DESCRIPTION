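Package: restconn
Title: Voxelwise Connectedness and Network Selectivity for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for resting-state functional MRI group studies
    of whole-brain connectivity. Computes voxelwise "connectedness" maps
    (Fisher-z of the mean Pearson correlation of each gray-matter voxel with
    every other gray-matter voxel), performs ANATICOR-style nuisance
    regression (motion parameters, ventricle mean, localized white-matter
    average, aCompCor components, polynomial baseline), quantifies head
    motion via mean frame-wise displacement, runs voxelwise group inference
    with a motion covariate and Benjamini-Hochberg FDR, defines regions of
    interest by cluster extent, builds ROI-ROI Fisher-z connectivity
    matrices, computes within-/between-network connectivity and network
    selectivity with ANCOVA and partial-correlation inference, and predicts
    behavior from connectivity features via PCA, ridge regression with
    leave-one-out cross-validation, and permutation testing. Includes a
    synthetic BOLD cohort generator with known network covariance structure
    for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
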