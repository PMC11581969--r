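Package: habitatrad
Title: Habitat Radiomics of Two-Phase Contrast CT for Tumor Immune-Marker
    Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for intratumoral habitat analysis of co-registered
    arterial- and venous-phase contrast-enhanced CT. Tumor regions of
    interest are partitioned into subregions ("habitats") by SLIC
    superpixels followed by K-means clustering of two-phase intensity
    profiles, with label harmonization across patients. IBSI-style
    radiomic features (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM)
    are extracted per habitat and per whole ROI, reduced by a staged
    pipeline (ICC robustness, distribution screen, Pearson pruning,
    cross-validated LASSO), and used to classify Tim-3 expression with
    ROC, calibration, Hosmer-Lemeshow and decision-curve evaluation.
    Includes an IHC H-score and survival arm (Kaplan-Meier, log-rank,
    survival-optimal cutpoints) and a fully specified synthetic-cohort
    generator with planted habitats for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    glmnet,
    ranger,
    xgboost,
    survival,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    jsonlite
Config/testthat/edition: 3
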