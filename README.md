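# habitatrad

Habitat radiomics of two-phase contrast-enhanced CT for modelling tumor
immune-marker (Tim-3) expression, with a pathology/survival arm and a fully
specified synthetic-cohort generator.

## What it does, and for whom

Radiomics models that treat the tumor region of interest (ROI) as one block
("Rad" models) can dilute biology that lives in a subregion. `habitatrad`
implements the habitat alternative for imaging scientists working with
co-registered arterial (ACE) and portal-venous (VCE) CT and a binary tumor
mask:

* **Habitat generation** — SLIC superpixels on the joint two-phase image
  inside the ROI, K-means (`k = 3` by default) on superpixel intensity
  profiles, small-region filtering, and *ReMap* label harmonization so
  habitat *k* means the same thing (the *k*-th least arterially enhancing
  subregion) in every patient.
* **Radiomic features** — an IBSI-style extractor (first-order, 3D shape,
  GLCM / GLRLM / GLSZM / NGTDM over the 13 unique 3D directions) applied to
  the whole ROI and per habitat, per phase, with early fusion into
  `<phase>__<region>__<family>__<feature>` columns. With a per-region,
  per-phase count F, the Rad table has `2F` columns and the per-habitat
  table `F x K x 2` (the familiar 1,834 → 3,668 / 11,004 accounting).
* **Staged feature selection** — ICC(2,1) robustness filter (min across
  test-retest and inter-rater designs, threshold 0.85), a distribution
  screen, Pearson pruning (|r| > 0.9), and LASSO logistic regression with
  10-fold cross-validated lambda.
* **Classification & evaluation** — logistic regression, random forest,
  extra trees, xgboost; ROC/AUC with bootstrap CIs, calibration with the
  Hosmer-Lemeshow test, decision-curve analysis, stratified 5-fold CV, and
  model ranking.
* **Pathology arm** — IHC H-score
  (`3·%HighPositive + 2·%Positive + 1·%LowPositive`, range 0–300),
  dichotomization at 92.3 (low inclusive), Kaplan-Meier / log-rank, and an
  X-tile-style survival-optimal cutpoint scan.
* **Synthetic cohorts** — two-phase volumes with three planted habitat
  shells, a class signal confined to one habitat and phase (whole-ROI mean
  nulled by construction), realistic between-patient nuisance, IHC fields,
  and exponential survival with a configurable hazard ratio. Every pipeline
  stage is tested against this ground truth.

## Worked example

```r
library(habitatrad)

cohort <- generate_cohort(cohort_spec(seed = 42))  # 102 patients, in memory

p   <- cohort$patients[[1]]
pre <- preprocess_patient(p$ace_volume, p$vce_volume, p$roi)
hab <- remap_labels(list(
  segment_patient(pre$ace, pre$vce, pre$roi, seed = 42)))$maps[[1]]
hab
#> <habitat_map> k = 3, voxels per habitat: 424, 1446, 2445

f <- extract_region_features(pre$ace, hab$labels == 2)
round(f[c("firstorder__mean", "glcm__contrast", "shape__volume_mm3")], 4)
#>  firstorder__mean    glcm__contrast shape__volume_mm3
#>            0.5535            0.4451         1446.0000
```

Harmonized habitat 2 of this patient is its middle-enhancement shell: 1,446
voxels (= mm³ at the 1 mm isotropic grid), mean normalized arterial
intensity 0.554 on the fixed −200…300 HU window, and a GLCM contrast of
0.45 on the 20-level quantization. The pathology arm works on plain numbers:

```r
h_score(ihc_field(50, 30, 20, 0))     # 3*50 + 2*30 + 1*20
#> [1] 230
followup_rates(102, 61)               # crude 5-year recurrence, percent
#> [1] 59.8

cl <- cohort$clinical
logrank(cl$os_months, cl$os_event, cl$tim3_class)[c("statistic", "p")]
#> $statistic
#> [1] 16.70298
#> $p
#> [1] 4.380699e-05
```

The planted hazard ratio of 2.2 between Tim-3 groups is clearly visible in
the 102-patient cohort's log-rank test. The central comparison — does the
habitat signature beat the whole-ROI signature on held-out patients? — is
one call:

```r
compare_signatures(seeds = 1:10)   # data.frame: seed, auc_rad, auc_habitat
```

which generates ten independent default cohorts, runs segmentation,
extraction, staged selection and a post-LASSO random-forest signature per
arm, and reports both test AUCs per seed (one to two minutes per cohort on
one CPU).

## Documentation

The methods vignette (`vignettes/habitat-radiomics-methods.Rmd`) documents
the models, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical edge-case policies,
and known limitations.
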