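Package: cxrsim
Title: Synthetic Chest Radiographs with Perfect Ground Truth and
    Lesion-Localization Reader-Study Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic posteroanterior chest radiographs by inserting
    augmented three-dimensional lung nodules into chest CT volumes and
    forward-projecting them with a parallel-beam projector, retaining exact
    per-lesion ground-truth masks. Converts Hounsfield units to linear
    attenuation, removes the patient table, and segments the lung from CT
    volumes; provides a synthetic thorax phantom generator so every stage is
    testable without patient data. Scores detector or human-reader mark lists
    against the generated ground truth using free-response ROC (FROC) and
    weighted alternative FROC (wAFROC) analysis, including the
    center-of-mass distance matching rule, equal per-case lesion weights, and
    the Wilcoxon-kernel figure of merit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    RNifti,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl
Config/testthat/edition: 3
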