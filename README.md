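# bivatlas

Statistical shape atlases of the two cardiac ventricles, and the question
they answer: **do atlas shape scores discriminate disease better than the
standard functional metrics** (volumes, mass, ejection fraction, strain,
MAPSE/TAPSE)?

The package is aimed at researchers in cardiac image analysis who work with
corresponded biventricular surface meshes at end-diastole (ED) and
end-systole (ES) — for example the output of an automated CMR segmentation
and model-fitting pipeline — plus a participant table with basic covariates.
Because large clinical mesh cohorts are access-restricted, the package also
ships a fully synthetic cohort generator with known ground truth, used both
for validation and for method study.

## What it computes

**Shape atlas.** ED meshes are co-registered by generalized Procrustes
alignment (rigid, no scaling; the ED transform is applied to both frames so
systolic motion survives in the shape vector). Each participant's aligned
ED and ES vertex coordinates are concatenated into a single vector
`x ∈ R^{2·3·V}` and a PCA atlas is fitted:

    x ≈ μ + Σ_k s_k φ_k

with orthonormal modes `φ_k` (descending eigenvalues `λ_k`, computed by SVD
of the centered data matrix, equivalent to the covariance
eigendecomposition with 1/(n−1) normalization). PC scores `s_k` are the
participant's coordinates in the atlas basis; components covering 90% of
variance (capped at 25) are retained.

**Standard metrics.** From each shape in native coordinates: LV/RV cavity
volumes by divergence-theorem integration over the closed labeled surfaces
(`Σ det[v0 v1 v2]/6`), LV mass (ED wall volume × 1.05 g/mL), ejection
fractions, geometric strain `((EDL − ESL)/EDL)·100` on endocardial rings
(GCS, mid-ventricular ring) and base-to-apex lines (GLS), MAPSE/TAPSE as
the mean 3D displacement of valve-ring vertices, and an Arts-formula
afterload index `SBP·(1 + 3·LVESV/LVWallVolume)` using
medication-adjusted SBP (+15 mmHg if treated).

**Quality control.** Composable gates: model-fit sanity (closed surfaces,
positive volumes, ESV < EDV), Mahalanobis distance in score space against a
chi-square quantile, rank-k projection error, and volume consistency
against an independent estimate — with a multi-criteria rejection report.

**Discrimination.** For each disease group vs the reference cohort,
two-class LDA models on PC scores and on standard metrics are compared via
stratified 5-fold cross-validated AUC (shared folds), the DeLong test on
the pooled out-of-fold scores, VIF pruning of collinear metrics (RV volume
removed first when an LV/RV volume pair is collinear), combined z-scores
(LDA discriminant standardized so the reference cohort is mean 0, SD 1),
and two-sample power calculations from the z-score effect sizes.

## Worked example

```r
library(bivatlas)
library(dplyr)

template <- build_template()                      # analytic biventricular anatomy
modes    <- build_mode_bank(template)             # size / motion / sphericity / contraction
spec     <- cohort_spec(n_reference = 80,
                        n_disease = c("Diabetes mellitus" = 30), seed = 42)
sim      <- simulate_cohort(template, modes, spec)

aligned <- generalized_procrustes(sim$shapes)
atlas   <- fit_atlas(do.call(rbind, lapply(aligned$shapes, concat_vector)))
atlas
#> <shape_atlas> 110 shapes, dim 8112, 109 modes (3 retained, 94.9% of variance)

scores  <- score_table(atlas, aligned$shapes)
metrics <- compute_metric_table(sim$shapes, sim$records)
round(colMeans(metrics[sim$records$group == "Reference",
      c("LVEDV","LVESV","LVM","LVEF","LV_GCS_mid","MAPSE","TAPSE")]), 1)
#>  LVEDV  LVESV    LVM   LVEF LV_GCS_mid  MAPSE  TAPSE
#>  148.7   72.0  127.8   51.7       24.9   12.6   17.9

res <- run_discrimination(scores, metrics,
                          select(sim$records, id, age, sex, bmi, height),
                          select(sim$records, id, group),
                          comparisons = "pc_vs_standard", seed = 1)
tidy(res)[, c("disease", "auc_pc", "auc_standard", "delong_p", "z_dz_mean_pc")]
#> # A tibble: 1 × 5
#>   disease           auc_pc auc_standard delong_p z_dz_mean_pc
#> 1 Diabetes mellitus  0.770        0.673  0.00585         1.22

power_two_sample(res$z_dz_mean_pc)$n_total
#> [1] 22
```

The reference-group means land near healthy adult CMR normals (LVEDV ~146
mL, LV mass ~123 g, LVEF ~54%, GCS ~27%, MAPSE ~12 mm) because the
synthetic template and mode variances are calibrated to them. The
discrimination row reads: PC scores separate the simulated diabetes group
from the reference better than the standard metric set (cross-validated
AUC 0.77 vs 0.67; DeLong p = 0.006 on this small cohort), and a study using
the combined PC z-score would need 22 participants total to detect the
group difference at alpha 0.05, power 0.8.

`autoplot(atlas)` draws the variance-explained scree;
`autoplot(res)` compares AUCs per disease; `tidy()`/`glance()` methods
cover the atlas, LDA models and discrimination results.

A YAML-driven pipeline (`cmd_simulate()`, `cmd_atlas()`, `cmd_metrics()`,
`cmd_qc()`, `cmd_discriminate()`, `cmd_all()`, with a thin CLI at
`inst/cli/bivatlas.R` and an example config in `inst/extdata/`) chains the
stages on disk with deterministic seeding.

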