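---
title: "Biventricular shape atlases and disease discrimination: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biventricular shape atlases and disease discrimination: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the places
where the design was genuinely open and a choice had to be made.

## 1. The statistical shape atlas

The atlas treats each heart as a point in a very high-dimensional space.
Every participant contributes a pair of corresponded triangulated surface
meshes — end-diastole (ED) and end-systole (ES), V vertices each, in mm —
covering the LV endocardium and epicardium and the RV endocardium and
epicardium, plus anatomical labels (valve rings, apex, short-axis rings,
base-to-apex lines).

ED frames are co-registered with **generalized Procrustes alignment
without scaling**: iterate rigid (Kabsch) alignment of every shape to the
evolving ED mean until the mean moves less than 1e-6 mm RMS (cap 100
iterations). Two choices deserve comment:

* *Consensus vs fixed reference.* Co-registration to an evolving consensus
  is the default because a consensus mean is the natural atlas origin; a
  fixed-reference single pass is available (`reference =` argument, or
  `alignment: reference` in the pipeline config) for incremental scoring
  of new cases against a frozen atlas.
* *The ED transform is applied to both frames.* Aligning ES independently
  would absorb systolic translation into the pose and destroy exactly the
  motion information (basal descent, MAPSE/TAPSE) that the concatenated
  vector is meant to carry.

The aligned ED and ES coordinates are flattened (x, y, z per vertex, ED
first) into a vector of length 2·3·V, and PCA is computed by SVD of the
centered data matrix — never by forming the 2·3·V square covariance — with
eigenvalues normalized by 1/(n−1). PC signs are fixed by making each
component's largest-magnitude loading positive; PCA signs are otherwise
arbitrary and scores would not be reproducible across runs. Retained
components: the smaller of 25 and the count reaching 90% cumulative
variance.

Score-space diagnostics: the **Mahalanobis distance**
sqrt(Σ s_k²/λ_k) and the rank-k **projection error** (RMS per-coordinate
residual of the rank-k reconstruction). Both feed the QC gates.

## 2. Functional metrics

All metrics are computed in native (pre-alignment) coordinates and are
rigid-motion invariant by construction.

* **Volumes** use the divergence theorem over closed labeled surfaces,
  Σ det[v0 v1 v2]/6, in mm³, reported in mL. Orientation is checked; an
  inward-oriented surface is flipped with a warning rather than silently
  negated. Open surfaces are an error that counts the unmatched edges.
* **LV mass** = ED wall volume (epi − endo) × density. Density defaults to
  1.05 g/mL, the standard CMR convention; it is exposed as a parameter
  because published values vary between 1.04 and 1.06 and some models
  include papillary structures in the cavity instead of the wall.
* **Geometric strain** = ((EDL − ESL)/EDL)·100, positive for contraction,
  on endocardial arc lengths. GCS uses the ring closest to 50% of
  cumulative base-to-apex distance — a concrete reading of
  "mid-ventricular", which is conventionally left undefined. GLS averages
  per-line strains rather than pooling lengths; per-line averaging is
  robust to unequal line lengths, and the pooled variant is available
  (`pooled = TRUE`) for sensitivity analysis (the two differ only when
  line lengths are unequal).
* **MAPSE/TAPSE** = mean over valve-ring vertices of the 3D displacement
  norm from ED to ES. The mean-of-norms convention (not the norm of the
  mean displacement) was chosen because it is the direct analogue of
  averaging per-point annular excursion measurements; the distinction
  matters when ring motion includes tilt, where the mean vector can
  understate excursion.
* **Afterload**: the printed product form SBP·(1 + 3·LVESV/LVWallVolume)
  is the default. The source formula's typography is ambiguous between
  this product and the logarithmic fiber-stress form
  3·SBP/ln(1 + 3·LVESV/LVWallVolume); both are implemented
  (`variant = "arts-log"`) and unit-tested, and the choice is a config
  flag rather than a silent guess. SBP is medication-adjusted (+15 mmHg
  when treated) before entering the formula.

## 3. The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which every cohort-level property in the test suite is evaluated.

**Template.** LV endo/epicardium are truncated prolate spheroids sharing a
long axis (endocardial semi-axes 26 × 55 mm, base truncation at 0.7·c,
wall 7.5 mm); the RV endocardium is a laterally attached shell with a
crescent cross-section (r(θ) modulated by 1 + 0.45·cos θ); the RV
epicardium is the endocardium offset 3 mm along outward normals — the
conventional fixed-thickness RV wall approximation. Each surface is closed
by a basal cap and an apex fan so volumes are well-defined. The ES frame
applies per-surface circumferential contraction about the long axis
(LV endo 0.27, RV endo 0.238, epicardia 0.12) plus basal descent with a
linear apex-to-base weight (LV 11.1 mm, RV 17.1 mm). These defaults were
calibrated once so the template's metrics land near healthy adult CMR
normals: LVEDV ≈ 144 mL, LVEF ≈ 53%, LV mass ≈ 123 g, LV GCS ≈ 27%,
MAPSE ≈ 12.2 mm, TAPSE ≈ 17.6 mm. The template has no outflow tract; the
"aortic" valve-ring label maps to the LV epicardial basal ring and is
annotation only — no metric consumes it.

One known limitation of the simple contraction + descent ES model: GLS
comes out near 14% rather than the ~21% of real hearts, because a linear
basal descent fixes the total longitudinal shortening at the descent
distance while real endocardial lines also shorten through wall thickening
and apical motion. GCS, EF, volumes, mass and MAPSE/TAPSE are all on
target; GLS is reported but not calibrated.

**Mode bank.** Four interpretable displacement fields over the
concatenated vector, Gram-Schmidt-orthonormalized in declared order:

1. *size* — radial scaling about each frame's centroid;
2. *motion* — ES-only extra basal descent with an annular-tilt modulation
   (relative amplitude `motion_tilt = 1.5`);
3. *sphericity* — long-axis shortening with short-axis widening, both
   frames;
4. *contraction* — ES-only endocardial inward displacement.

Orthogonalization mixes a small amount of earlier fields into later ones
(e.g. the orthonormal motion mode carries a slight ED size component);
this is accepted as the price of an exactly orthonormal planted basis.

The tilt term in the motion mode is a deliberate design decision. Real
basal systolic motion is regionally non-uniform — septal and lateral
annular excursion differ clinically — and a ring-averaged excursion such
as MAPSE is only second-order sensitive to the tilt component (the mean of
displacement norms changes at order tilt²/descent). A spatially uniform
descent mode would be essentially fully visible through MAPSE/TAPSE, and a
"motion-shifted" disease group would then be equally separable by standard
metrics and by PC scores, leaving nothing of the scientific question to
study in silico. With the tilt, roughly half the motion-mode variance is
invisible to the standard metric set at first order, so the generator can
pose the question the package exists to answer. Empirically, MAPSE
correlates with the motion score at r ≈ 0.5 under the default settings.

**Variances.** Mode score variances default to 170², 97², 82², 30²
(score units are mm along each unit-norm field). The first three are in
the proportions 34 : 11 : 8, mirroring the leading variance fractions
reported for population cardiac shape atlases, and the size variance is
scaled so LVEDV spreads with SD ≈ 32 mL; the contraction variance was set
to give a physiologic LVEF SD (≈ 7%) rather than continuing the geometric
progression, which would have produced EF swings no screening cohort
shows. With these defaults the planted fractions are 0.62/0.20/0.14/0.02
and three components reach 90% variance — a controllable ground truth for
the component-count rule.

**Cohort.** Per participant, mode scores are group mean + covariate
contribution + Gaussian residual; the shape is template + Σ score·mode +
iid vertex jitter (default SD 0.5 mm, a typical surface-fitting residual).
Covariates follow a documented linear-Gaussian model: sex and height load
on the size mode (0.35 SD for male sex, 0.025 SD per cm), age loads
weakly against motion; disease groups are older, more often male, heavier
and have higher blood pressure, and are shifted along the modes by
disease-specific offsets in SD units. The default shifts encode the
qualitative clinical pattern (reduced motion and contraction everywhere,
enlargement in most groups, dilated cardiomyopathy most severe); the
diabetes shift is calibrated so the combined PC z-score of the disease
group sits near 1.0. Effect directions are clinically grounded;
magnitudes are documented defaults, not estimates of any real cohort.
All randomness flows from a single integer seed, and the generator is a
pure function of (template, modes, spec, seed).

**What the generator does not emulate:** image acquisition and
segmentation error structure (jitter is iid, real errors are spatially
correlated), trabeculation and papillary anatomy, outflow tracts,
nonlinear shape–covariate relationships, co-morbidity structure, and
longitudinal change. Passing tests on this generator therefore validate
the *machinery* — alignment, PCA recovery, metric computation, the
statistical protocol — under a known linear ground truth; they do not
certify performance on real CMR meshes. One visible consequence of the
linear 4-mode world: standard metrics see most of any planted disease
shift (the modes are global), so synthetic standard-model z-scores can
exceed their real-data counterparts.

## 4. Quality control

Gates are pure functions, applied after a single atlas fit on fit-passing
shapes (the alternative — iterating QC and refitting — is defensible but
under-specified; one fit keeps the pipeline deterministic and auditable):

* fit gate: finite coordinates, closed labeled surfaces, positive cavity
  and wall volumes, ESV < EDV per ventricle;
* Mahalanobis gate: squared score distance vs the chi-square
  (1 − α) quantile at k degrees of freedom, α = 0.001 by default;
* projection gate: rank-k RMS projection error vs a threshold calibrated
  as median + 5·MAD of the training errors;
* volume gate: relative deviation from an independent LVEDV (ground truth
  in the synthetic pipeline; an independent measurement with real data),
  tolerance 20%, boundary passes.

The report counts per-criterion and union rejections; the union is never
larger than the sum (cases commonly fail several gates at once), and that
invariant is asserted on every pipeline run.

## 5. Discrimination statistics

* **LDA** is the package's own pooled-covariance implementation (weights
  solve(Σ_pooled, μ₁ − μ₀), class-frequency priors; ridge jitter
  1e-8·trace/p only on singularity). An independent library
  implementation serves as a cross-check in the tests, never as the
  implementation.
* **Cross-validated AUC**: stratified k-fold (both classes in every
  fold), out-of-fold discriminant scores pooled into one ROC, AUC as the
  Mann-Whitney statistic with ties counted ½. The two compared models
  always share the fold assignment — otherwise fold noise would leak into
  the model comparison and the DeLong test on pooled scores would not be
  coherent.
* **DeLong test**: structural-components (midrank) estimate of
  var(AUC_a − AUC_b) accounting for the correlation induced by scoring
  the same cases; two-sided normal p. Applied to the pooled out-of-fold
  scores, treating them as a single ROC.
* **VIF pruning**: iterative removal until all VIFs < 5; when both an LV
  and an RV volume measure exceed the threshold the RV one is removed
  first (the anatomically motivated pair rule); exact collinearity counts
  as infinite VIF; ties break by column order, so pruning is
  deterministic.
* **Combined z-score**: the LDA discriminant projection standardized by
  the reference subset (mean 0, SD 1 by construction — asserted to 1e-9
  on every run), sign oriented so the disease mean is positive.
* **Power**: n_per_group = 2·(z_{1−α/2} + z_{power})²/d², rounded to the
  nearest integer, with d = the disease-group mean combined z-score. This
  normal-approximation-plus-nearest-integer convention is the unique
  simple rule consistent with the published example totals (d = 0.99 →
  32 total; d = 0.68 → 68 total) and is stated prominently because power
  conventions differ (t-based formulas and ceiling rounding give 34/70).

Wilcoxon rank-sum tests (exact for small tie-free samples, corrected
normal approximation otherwise — the behavior of R's `wilcox.test`),
Pearson correlations and OLS regressions cover the univariate analyses.

## 6. Numerical choices and degenerate inputs

* Procrustes tolerance 1e-6 mm RMS; Kabsch determinant correction
  guarantees a proper rotation (reflections are rejected even when they
  fit better).
* PCA rank cutoff: eigenvalues below 1e-12 of the leading eigenvalue are
  discarded as numerical zeros.
* Volume of a non-closed surface, zero-magnitude vertex normals, repeated
  consecutive path indices, non-positive wall volumes, single-class LDA
  inputs, and empty reference subsets are all hard errors with named
  causes, not NaN propagation.
* The DeLong variance can be numerically zero when two score vectors are
  identical; the statistic is defined as z = 0, p = 1 in that case.

## 7. Problem sizes used in validation

The test suite and the acceptance script run the full pipeline at
deliberately desk-scale sizes: template resolutions of 8 rings × 16
points (V = 520) for cohort-level experiments and 12 × 28 (V = 1352) for
calibration checks; cohorts of 100–500 for recovery properties and
2000 + 500 for the discrimination experiment; 2000 Monte-Carlo replicates
for the DeLong type-I calibration. These sizes were chosen as the
smallest at which the targeted statistical properties are comfortably
identifiable; all scale linearly if larger studies are needed.

## 8. Known limitations

* The linear mode model cannot represent localized (regional) disease
  remodeling; PC-vs-standard comparisons on synthetic data understate the
  advantage atlas scores show on real cohorts with regional pathology.
* GLS is systematically low in the template (see §3).
* QC thresholds are calibrated on synthetic data; real deployments should
  recalibrate the projection-error and volume-consistency gates on their
  own reference population.
* The DeLong comparison at n = 2000 + 500 with a 1 SD motion-only shift
  has moderate power: the AUC advantage of PC scores is consistent in
  direction but its significance varies across simulation seeds.
* Septal mass allocation between LV and RV is not modeled; the LV wall
  volume includes the whole septum.
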