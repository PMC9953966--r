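Package: tauradiomics
Title: Radiomics Texture Analysis and Classification for Tau PET Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for radiomics classification of tau PET
    imaging cohorts. From spatially normalized 3D PET volumes and an
    integer-labeled atlas it defines disease-related regions of interest by
    voxelwise two-sample t-tests with false-discovery-rate and cluster-extent
    thresholding, quantizes regional uptake with the Lloyd-Max algorithm,
    extracts a 43-feature texture bank (histogram, GLCM, GLRLM, GLSZM,
    NGTDM) per region, screens features by correlation and t-test filters,
    and classifies subject groups with a linear support vector machine under
    repeated stratified cross-validation, alongside SUVR and clinical-score
    comparator models. A synthetic-cohort generator produces phantom atlases
    and subject volumes with injected regional mean and texture effects so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
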