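Package: rimla
Title: Repeatability-Informed Longitudinal Assessment of Brain Lesions
    with Quantitative MRI Normative Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing multiple sclerosis lesions from
    quantitative MRI. Classifies lesions into longitudinal phenotypes
    (new, enlarging, shrinking, stable) with a repeatability-informed
    bootstrap slope analysis that propagates the scan-rescan coefficient
    of variation of the segmentation into the inference. Builds voxelwise
    age- and sex-adjusted normative atlases of T1, T2 and T2/T1
    relaxometry values, converts patient maps into z-score deviation
    maps, delineates perilesional rings from exact anisotropic Euclidean
    distance transforms, extracts per-lesion microstructural feature
    vectors, and reproduces the downstream univariate (aligned-rank
    ANOVA) and multivariate (balanced random forest) analyses. A
    synthetic-data module generates all inputs with the statistical
    structure the analysis assumes, so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    optparse
Config/testthat/edition: 3
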