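# radstrat

Radiomics-based two-class cancer risk stratification in R.

Quantitative texture descriptors computed from tumour regions of interest
(ROIs) on paired imaging modalities — a T2-weighted-like structural image and
an ADC-like diffusion map — can separate high-risk from lower-risk tumours
where visual reading is subjective. `radstrat` implements the complete
analysis as a tested pipeline:

1. **Texture feature extraction** — 55 features per modality (110 per
   patient) from four families: first-order histogram statistics; Haralick
   features of the gray-level co-occurrence matrix (GLCM), averaged over the
   four unit-distance directions; gray-level difference matrix (GLDM)
   statistics; and Fourier power-spectrum descriptors. The feature manifest
   is frozen and versioned.
2. **Classifier benchmarking** — seven algorithms (logistic regression;
   linear, quadratic, cubic and Gaussian kernel SVMs; LDA; random forest)
   under repeated stratified 5-fold cross-validation (10 repetitions) with
   random oversampling of the minority class applied to training folds only.
3. **Model selection** — Friedman–Nemenyi rank analysis across the 10 CV
   runs over seven measures (AUC plus F\_max/P\_max/R\_max for each class),
   with critical difference CD = q\_α · √(k(k+1)/6N); the algorithm in the
   top statistical group of every measure with the lowest grand mean rank is
   selected.
4. **Final classifier** — the selected learner refit on the oversampled
   development set; its decision threshold is the mean of the per-run
   thresholds that maximized the high-risk F-measure
   (F\_max = max\_t 2·P(t)·R(t)/(P(t)+R(t))).
5. **Independent validation** — comparison against an ordinal 1–5
   reader-score benchmark (binarized at score > 3), a 100-fold
   label-permutation null, and paired-bootstrap Friedman p-values per
   measure, assembled into a three-row benchmark table.

Because comparable patient imaging is rarely shareable, the package ships a
seeded synthetic-cohort generator (Gaussian-random-field textures with
class- and modality-specific parameters, binary risk labels, correlated
ordinal reader scores) that reproduces the statistical structure the
analysis assumes: a 68-patient development cohort (54 lower-risk / 14
high-risk) and a 53-patient validation cohort (39 / 14), with a single
`effect_size` knob scaling the class separation.

## Worked example

```r
library(radstrat)

res <- run_pipeline(
  dev_spec = cohort_spec(n_high = 14, n_lower = 54, seed = 101),
  val_spec = cohort_spec(n_high = 14, n_lower = 39, seed = 102),
  runs = 10, folds = 5, seed = 1, use_images = TRUE, replicates = 100
)

res$selection$algorithm
#> [1] "LogReg"
round(sort(res$selection$grand_mean_ranks), 2)
#> LogReg   LSVM   QSVM   GSVM     RF   CSVM    LDA
#>   2.39   3.21   3.64   3.84   4.02   4.70   6.20
res$analyses$auc$nemenyi_cd
#> [1] 2.848348
res$final$threshold
#> [1] 0.641831
print(res$validation$report)
#> | method | auc | fmax_high | pmax_high | rmax_high | fmax_lower | pmax_lower | rmax_lower |
#> |---|---|---|---|---|---|---|---|
#> | classifier | 0.916 (6.63e-09) | 0.800 (1.55e-05) | 0.909 (1.52e-23) | 0.714 (4.18e-23) | 0.938 (7.97e-18) | 0.905 (4.18e-23) | 0.974 (1.52e-23) |
#> | comparator | 0.874 | 0.737 | 0.583 | 1.000 | 0.853 | 1.000 | 0.744 |
#> | permutation null | 0.504 (0.00893) | 0.235 (0.00997) | 0.267 (0.0113) | 0.210 (0.0089) | 0.764 (0.00308) | 0.737 (0.00297) | 0.793 (0.00319) |
```

Reading the output: on this synthetic cohort the rank analysis selects
ridge-penalized logistic regression (lowest grand mean rank 2.39, inside the
critical difference of the best algorithm on all seven measures). The final
classifier, thresholded at the averaged F\_max threshold 0.64, reaches AUC
0.916 on the independent validation cohort versus 0.874 for the ordinal
reader-score comparator; the parenthesized values in the classifier row are
paired-bootstrap Friedman p-values against the comparator, and the
permutation-null row shows that label shuffling collapses the AUC to 0.504
(standard errors over the 100 permuted copies in parentheses) — the
classifier captures a real feature–label relationship.

Individual stages are exposed directly: `generate_cohort()` /
`write_cohort()` / `read_cohort()` for data, `extract_patient()` /
`extract_cohort()` for features, `run_cv()`, `rank_analysis()`,
`select_best()`, `train_final()` for model selection, and
`permutation_benchmark()`, `bootstrap_compare()`, `build_report()` for
validation.

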