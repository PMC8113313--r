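Package: radphen
Title: Radiomic Phenotyping of CT Tumor Features with Survival Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives radiomic tumor phenotypes from CT feature matrices by
    two-level consensus hierarchical clustering (feature-level clustering on a
    1 - r^2 correlation distance with CDF delta-area selection of the number of
    clusters, first-principal-component signatures per feature cluster, then
    tumor-level consensus clustering with a SigClust significance test), and
    quantifies the phenotypes' added prognostic value over clinical and ctDNA
    covariates with Cox proportional-hazards models, likelihood-ratio tests and
    the inverse-probability-of-censoring-weighted (Uno) concordance statistic.
    Includes a documented 3D radiomic feature extractor (first-order, shape,
    GLCM, GLRLM, GLSZM, GLDM, NGTDM, Laplacian-of-Gaussian and Haar wavelet
    families) and a synthetic-cohort generator with planted ground truth so
    every pipeline stage has a parameter-recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
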