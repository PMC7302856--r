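# prosrsa

Representational similarity analysis (RSA) of how prosthetic limbs are
represented in category-selective visual cortex, for researchers studying
wearable-device adoption, limb loss, and visual category learning with
multivoxel fMRI patterns.

The scientific question the package operationalises: when one-handed
prosthesis users view hands, tools, cosmetic prostheses, and active
prostheses, does their occipitotemporal cortex represent prostheses like
hands (embodiment), like tools, or as a category of their own — and does
this scale with everyday prosthesis usage?

## What it computes

* **Crossnobis RDMs.** Per-subject condition × condition distance matrices
  using leave-one-run-out cross-validated Mahalanobis distances (the linear
  discriminant contrast), after multivariate noise normalisation with a
  shrinkage covariance estimated from GLM residuals:
  `d(a,b) = mean over folds of  δ̄_train' δ_test / V`, with `V` the voxel
  count. The estimator is unbiased, so null distances average to zero and
  single estimates can be negative.
* **Two contrast indices** per subject (with `X↔Y` a crossnobis distance,
  `H` hands, `T` tools, `CP`/`AP` cosmetic/active prostheses):
  * hand-similarity (embodiment): `(T↔CP + T↔AP) − (H↔CP + H↔AP)`
  * prosthesis-similarity (categorisation):
    `3(H↔CP + T↔AP) − 2(H↔AP + T↔CP + AP↔CP)`

  both residualised on the subject's `H↔T` distance to remove overall
  pattern-scale differences.
* **Own-prosthesis normalised distances** — a user's own-prosthesis↔hand
  (↔tool) distance divided by the control-group mean distance of the
  matched generic prosthesis condition (1 = at the control baseline).
* **Usage scoring** — prosthesis activity log (27 items, 0–2, scored /54),
  wear frequency (max across prosthesis types, 0–5), their population-z
  composite, and primary-prosthesis classification.
* **The statistics layer** — pooled-variance t tests, bootstrapped Pearson
  correlations, Steiger's Z1* for dependent correlations, Type III ANCOVA,
  one- and two-tailed JZS Bayes factors (Cauchy scale 0.707), and PCA of
  pairwise distances.
* **A synthetic-cohort generator** with planted representational
  geometries (natural-category controls versus a usage-coupled prosthesis
  cluster in users), so the entire pipeline is testable without imaging
  data.

## Worked example

Simulate a small cohort and run the full pipeline (ROI selection → noise
normalisation → crossnobis RDMs → indices → statistics):

```r
library(prosrsa)

cfg <- pipeline_config(
  sim = sim_config(n_controls = 12, n_users = 16, n_voxels = 60,
                   n_residual_timepoints = 60, seed = 7),
  n_boot = 1000
)
report <- run_pipeline(cfg)
dplyr::select(report$stats, analysis, estimate, statistic, df1, p_value, bf10)
#> # A tibble: 10 × 6
#>    analysis                         estimate statistic   df1      p_value   bf10
#>  1 hand_similarity_group              0.0541     0.223    26 0.825        NA
#>  2 prosthesis_similarity_group      -11.5       -6.80     26 0.000000321  NA
#>  3 hand_similarity_group_bf          NA          0.223    26 0.825         0.308
#>  4 usage_vs_hand_similarity           0.306      0.306    14 0.249        NA
#>  5 usage_vs_prosthesis_similarity     0.942      0.942    14 0.0000000517 NA
#>  6 dependent_correlation_comparison  -0.636     -3.61    Inf 0.000302     NA
#>  7 subgroup_ancova_factor            NA          3.88      1 0.0704       NA
#>  8 subgroup_ancova_usage             NA        136.        1 0.0000000289 NA
#>  9 own_hand_vs_1                      1.44       4.38     13 0.000748     NA
#> 10 own_tool_vs_1                      1.67       4.60     13 0.000494     NA
```

Reading the table: the generator plants a prosthesis-cluster geometry in
users that strengthens with usage, and an embodiment null. The pipeline
recovers exactly that dissociation — no group difference in hand-similarity
(row 1; the Bayes factor in row 3 leans towards the null) but a strong group
difference in prosthesis-similarity (row 2), a usage correlation for
categorisation but not embodiment (rows 4–5, compared formally in row 6),
usage-driven rather than subgroup-driven indices (rows 7–8), and
own-prosthesis distances above the control baseline of 1 (rows 9–10).

The usage-scoring chain reproduces the published cohort table from its raw
columns:

```r
tb <- reproduce_usage_table()
dplyr::select(tb, subject_id, pal, wear_frequency, usage_score,
              usage_score_printed, primary_class)[1:3, ]
#> # A tibble: 3 × 6
#>   subject_id   pal wear_frequency usage_score usage_score_printed primary_class
#> 1 01          0.57              5       2.99                 2.99 cosmetic
#> 2 02          0.46              4       1.92                 1.92 cosmetic
#> 3 03          0                 0      -2.42                -2.42 non_user
sum(tb$usage_score_match)
#> [1] 32
```

and the Bayes-factor worked example evaluates to the published rounded
value:

```r
jzs_bayes_factor_t(0.47, n1 = 32, n2 = 24, alternative = "less")
#> [1] 0.2001652
```

## Package tour

| Area | Functions |
| --- | --- |
| Synthetic cohorts | `sim_config()`, `geometry_template()`, `embed_geometry()`, `simulate_subject()`, `simulate_cohort()` |
| ROI | `select_top_voxels()`, `mean_roi_activity()`, `subset_to_roi()`, `read_roi_volumes()` |
| RSA core | `estimate_noise_covariance()`, `prewhiten()`, `crossnobis_rdm()`, `mean_rdm()`, `linkage_dendrogram()` |
| Indices | `hand_similarity_index()`, `prosthesis_similarity_index()`, `standardize_by_hand_tool()`, `compute_similarity_indices()`, `replace_active_distances()`, `own_prosthesis_normalized()` |
| Usage | `pal_score()`, `wear_frequency()`, `usage_score()`, `classify_primary()`, `reproduce_usage_table()`, `by_type_subgroups()` |
| Statistics | `two_sample_t()`, `one_sample_t_vs()`, `pearson_r_bootstrap()`, `compare_dependent_correlations()`, `ancova_fixed_plus_covariate()`, `jzs_bayes_factor_t()`, `pca_pairwise_distances()` |
| Pipeline & plots | `pipeline_config()`, `run_pipeline()`, `subject_rdm()`, `autoplot()` on RDMs, `plot_index_vs_usage()`, `plot_dendrogram()` |

Fitted results are tibbles or carry broom-style `tidy()`/`glance()`
methods throughout. See `vignettes/prosthesis-rsa-methods.Rmd` for the full
account of the model, the planted-geometry conventions, parameter defaults,
and known limitations.
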