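# ipithsurv

Multi-lesion CT radiomics, intra-patient inter-tumor heterogeneity (IPITH)
metrics, and survival machine-learning benchmarks for progression-free
survival (PFS) — the setting is metastatic lung adenocarcinoma under
first-line immune checkpoint inhibitors, where most radiomics models look at
one lesion while the disease is multi-focal.

The package is aimed at imaging/biostatistics researchers who want a tested,
reusable R implementation of the whole chain:

* **Feature extraction** (NIfTI volumes + masks): resampling to 1 × 1 × 2 mm,
  discretization into 120 gray levels of 2.5 HU over [−100, +200] HU, and
  IBSI-aligned histogram, shape, GLCM, GLRLM, GLSZM features over the 13
  unique 3-D directions; erosion-based ICC(2,1) robustness filtering
  (keep iff ICC > 0.85), near-zero-variance removal, center scaling.
* **Per-patient aggregation**: largest-lesion features; elementwise
  min/avg/max over lesions; and IPITH — for a patient with lesions
  x₁…x_k in the d-dimensional robust-feature space, the pairwise distances
  D = {d(xᵢ, xⱼ) : i < j} under Euclidean, Chebyshev, Minkowski (p = 3),
  Canberra (Σ|aᵢ−bᵢ|/(|aᵢ|+|bᵢ|)), Spearman (1 − ρ), and generalized
  Jaccard, summarized as min(D), mean(D), max(D), range(D).
* **Screening**: univariable Cox (Efron ties) and log-rank tests; strict
  p < 0.100 filter into the *clinicopathological* / *full* inputs; Spearman
  pruning (p < 0.05, descending |ρ|, clinicopathological variables
  privileged over radiomics) into the *uncorrelated* input.
* **Five survival learners behind one contract** (risk score + survival
  curve): backward stepwise-AIC Cox, LASSO Cox (glmnet), random survival
  forest (ranger, 1000 trees, log-rank splits), Cox gradient boosting
  (xgboost `survival:cox`), and a **natively implemented Deepsurv** — a
  feed-forward network trained on the negative log Cox partial likelihood
  `−Σ_events [s_i − log Σ_{j∈R(t_i)} e^{s_j}]` with batch-wise risk sets,
  batch norm, dropout, early stopping, and exact (numerically verified)
  gradients. With zero hidden layers and full batches it recovers Cox
  regression.
* **Evaluation**: event-stratified 100 × 5-fold repeated cross-validation
  (112-patient training partitions / 28-patient test folds at n = 140),
  Harrell's c-index, IPCW time-dependent Brier score and integrated Brier
  score on the 3-month grid to 24 months, paired Wilcoxon comparison of
  c-index distributions, and permutation importance scaled to 100%.
* **Synthetic data**: seeded textured lesion phantoms and multi-lesion
  cohorts (140 patients, 2–15 lesions each, 68 features, ~82.9% events,
  median PFS ~6 months) with a hierarchical feature model whose
  `heterogeneity_scale` makes the true per-patient Canberra-mean a known
  ground-truth hazard driver.

## Worked example

```r
library(ipithsurv)

cfg <- pipeline_config(
  sim_config = cohort_sim_config(n_patients = 140, seed = 1),
  plan = cv_plan(repetitions = 5, folds = 5, seed = 1),
  seed = 1
)
report <- run_pipeline(cfg)
print(report)
```

```
Multi-lesion radiomics survival pipeline report
  cohort: 140 patients / 644 lesions
  input sets: clinicopathological (3), full (31), uncorrelated (10)
  rCV mean c-index by model.input:
    lasso_cox.uncorrelated       0.686 (0.674-0.695)
    stepwise_cox.uncorrelated    0.676 (0.663-0.690)
    lasso_cox.full               0.668 (0.646-0.684)
    gbm.uncorrelated             0.652 (0.631-0.664)
    deepsurv.uncorrelated        0.648 (0.633-0.675)
    rsf.uncorrelated             0.646 (0.622-0.677)
    stepwise_cox.full            0.644 (0.637-0.649)
    rsf.full                     0.644 (0.622-0.664)
```

Reading the output: the simulated cohort's univariable screen kept 31
variables at p < 0.100, of which 3 are clinicopathological; correlation
pruning reduced the full input to 10 variables

```r
report$input_sets$uncorrelated
#>  [1] "who_ps"        "met_sites"     "bone_mets"     "largest_rf_06"
#>  [5] "min_rf_14"     "avg_rf_01"     "max_rf_28"     "max_rf_43"
#>  [9] "max_rf_67"     "spearman_min"
```

and each model × input pair is summarized by its mean test c-index over the
repeated cross-validation with a 2.5–97.5 percentile interval over
repetitions (0.5 = random ranking, 1 = perfect). On this synthetic draw the
radiomics-augmented inputs clearly beat the clinicopathological-only models
(not shown in the top rows above), reflecting the generator's built-in
lesion-feature and heterogeneity effects.

The image path uses the same machinery from NIfTI pairs:

```r
les <- generate_textured_lesion(volume_sim_config(seed = 1))
f <- extract_features(les$volume, les$mask, les$voxel_size)
f[c("glszm_nzsn", "glrlm_lre", "hist_entropy_log2")]
```

## Package layout

| Area | Functions |
|---|---|
| Synthetic data | `volume_sim_config`, `generate_textured_lesion`, `cohort_sim_config`, `generate_cohort`, `generate_survival_times`, `write_cohort_csv` |
| Extraction | `resample_volume`, `discretize_volume`, `erode_mask`, `extract_features`, `compute_*_features`, `texture_directions` |
| Filtering | `icc21`, `icc_robustness_filter`, `near_zero_variance_filter`, `center_scale` |
| Aggregation | `select_largest_lesion`, `summarize_min_avg_max`, `pairwise_lesion_distance`, `ipith_summaries`, `patient_predictor_table` |
| Screening | `fit_univariable_cox`, `logrank_test`, `kaplan_meier`, `univariable_screen`, `filter_candidates`, `prune_correlated` |
| Models | `model_spec`, `fit_survival_model`, `fit_stepwise_cox`, `fit_lasso_cox`, `fit_rsf`, `fit_gbm`, `fit_deepsurv`, `deepsurv_config`, `predict_risk`, `predict_survival` |
| Evaluation | `harrell_cindex`, `brier_score`, `integrated_brier_score`, `repeated_stratified_cv`, `compare_cindex_distributions`, `permutation_importance` |
| Orchestration | `pipeline_config`, `read_pipeline_config`, `validate_inputs`, `run_pipeline` |

See the vignette (`vignettes/multilesion-radiomics-survival.Rmd`) for the
model descriptions, the distance-metric definitions on signed data, the
synthetic-cohort design and its limitations, and every numerical convention.
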