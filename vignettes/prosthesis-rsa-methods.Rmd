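---
title: "Methods: representational similarity analysis of prosthesis embodiment and categorisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis of prosthesis embodiment and categorisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosrsa)
```

## The scientific question

When a person uses a prosthetic limb, does their visual cortex come to
represent it as a hand (embodiment), as a tool, or as a category of its own?
`prosrsa` implements the multivoxel analysis pipeline for this question:
condition-wise fMRI beta patterns from a body-selective occipitotemporal
region of interest (ROI) are compared across four conditions — hands,
cosmetic prostheses (hand-like in appearance), active prostheses
(grip-affording, tool-like), and hand-held tools — in one-handed prosthesis
users and two-handed controls. Two signed contrasts of the pairwise pattern
distances operationalise the competing hypotheses, and their relationship
with a composite everyday-usage score provides the use-dependence test.

## Distance model: crossnobis / linear discriminant contrast

For each subject, each of $R$ runs yields one beta pattern per condition over
the ROI voxels. Patterns are first noise-normalised: the voxel covariance
$\Sigma$ is estimated from the run-wise GLM residuals (per-run sample
covariances averaged, then shrunk towards their diagonal), and all patterns
are multiplied by $\Sigma^{-1/2}$ so that noisy, correlated voxels are
down-weighted. The shrinkage weight is the analytic
(Ledoit–Wolf/Schäfer–Strimmer-style) ratio of the summed sampling variances
of the off-diagonal covariances to their summed squares, clipped to
$[0, 1]$; it can be overridden, and forcing it to 1 yields a purely diagonal
(univariate) normalisation.

The distance between conditions $a$ and $b$ is the leave-one-run-out
cross-validated Mahalanobis distance (the linear discriminant contrast):

$$
d_{ab} \;=\; \frac{1}{R}\sum_{f=1}^{R}
\frac{\bar\delta_{\setminus f}^{\top}\,\delta_{f}}{V},
\qquad
\delta_f = \tilde\beta_{f,a} - \tilde\beta_{f,b},
$$

where $\tilde\beta$ are prewhitened patterns, $\bar\delta_{\setminus f}$ is
the mean pattern difference over the training runs, and $V$ is the voxel
count. Dividing by $V$ makes the units independent of ROI size. Because the
training and test differences carry independent noise, the estimator is
unbiased: its expectation is zero for identical true patterns, and single
estimates can legitimately be negative. The test suite verifies exact
agreement with a brute-force fold-enumeration oracle and the null
unbiasedness by simulation.

Group-level structure is visualised with an agglomerative linkage tree built
on the group-mean RDM. Average linkage (UPGMA) is the default; no particular
linkage is canonical for condition trees, so the method is exposed as a
parameter. Negative cross-validated distances are clipped to zero for tree
construction only, with a warning.

## ROI selection

Subject-specific ROIs take the `n_per_hemisphere` (default 250) voxels with
the largest localizer statistic (headless bodies > objects) per hemisphere,
inside an anatomical mask; both hemispheres are then pooled into a single
ROI. The statistic map is treated as opaque (any monotone transform gives the
same selection), and ties at the cutoff are broken by ascending voxel index
so selection is deterministic. Setting `n_per_hemisphere = NULL` keeps the
whole mask, which is how purely anatomical ROIs (e.g., an intraparietal
sulcus mask) enter the same pipeline.

## The two indices

With $H$, $T$, $CP$, $AP$ denoting hands, tools, cosmetic and active
prostheses, and $X\!\leftrightarrow\!Y$ a crossnobis distance:

* **Hand-similarity (embodiment) index**
  $(T\!\leftrightarrow\!CP + T\!\leftrightarrow\!AP) -
   (H\!\leftrightarrow\!CP + H\!\leftrightarrow\!AP)$.
  Positive when prostheses sit closer to hands than to tools. It is exactly
  the negative of the analogous tool-similarity contrast, so significant
  negative values indicate tool-like representation.
* **Prosthesis-similarity (categorisation) index**
  $3(H\!\leftrightarrow\!CP + T\!\leftrightarrow\!AP) -
   2(H\!\leftrightarrow\!AP + T\!\leftrightarrow\!CP +
     AP\!\leftrightarrow\!CP)$.
  Distances expected to grow when prostheses form their own cluster carry
  positive weights, those expected to shrink carry negative weights, and the
  weights balance so that any equal-distance RDM scores zero.

Both indices are linear in the RDM, so overall pattern-scale differences
between subjects propagate into them. To control for this, each index is
residualised on the subject's hands–tools distance (OLS with intercept). The
residualisation is fitted across the pooled cohort by default: the
downstream group comparisons need a shared baseline, and within-group
fitting would remove exactly the group difference being tested. A
`by_group` option implements the alternative, and raw indices are always
emitted alongside. If the covariate is constant the regression is undefined
and the function falls back to mean-centering with a warning.

### Own-prosthesis distances

Users who were shown their own prosthesis get an additional condition. Since
controls own no prosthesis, a user's own-to-hands (own-to-tools) distance is
divided by the control-group mean distance between the *matched* generic
prosthesis condition and hands (tools). A value of 1 means the user
represents their own prosthesis exactly as controls represent a
similar-looking one. Matching is by prosthesis type by default (cosmetic own
prostheses to the generic cosmetic condition, active ones to the generic
active condition); the `hand_likeness` rule re-matches visually hand-like
active prostheses to the cosmetic condition, covering both appearance and
operation. Cohort inference is a one-sample t test against 1.

### Mixed-exemplar correction

A subset of users viewed a visually different exemplar in the
active-prosthesis condition. Two remedies are implemented: replacing the
three active-prosthesis distances of affected subjects with the mean of the
unaffected users, or excluding the subjects entirely. Both leave every other
entry untouched, which the tests check explicitly.

## Usage scoring

The prosthesis activity log (PAL) rates 27 daily activities 0–2 and is
scored as the item sum over 54, giving $[0, 1]$. Wear frequency is rated 0–5
per prosthesis type and the maximum across types is used. The composite
usage score is the sum of the cohort z-scores of the two measures. The
z-transform uses the **population convention (divisor $n$)**: this is the
single scoring choice the printed cohort table pins down empirically — with
divisor $n$ the recomputed composite matches all 32 printed values at two
decimals, while the sample convention ($n-1$) misses by up to 0.05. The
regression test asserts all 32 matches; any mismatch is surfaced, never
absorbed.

Primary-prosthesis classification takes the type with the highest wear
rating (all-zero → non-user; tied non-zero maximum → hybrid). For the
by-type analyses the single hybrid user is grouped with active users by
default: with the stated exclusions (non-users and the five
different-exemplar viewers) this reproduces the analysed subgroup sizes of
13 cosmetic versus 9 active users, which an exclusion rule would not
(13 versus 8). The exclusion rule remains available as an option.

## Statistics layer

* Group comparisons: pooled-variance Student t (df $= n_1+n_2-2$, matching
  the reporting convention), two-tailed.
* Correlations: Pearson r with the analytic t-based p and a seeded
  percentile bootstrap CI (default 10,000 paired resamples).
* Comparing the two usage correlations: Steiger's Z1* for dependent
  correlations sharing one variable, with the covariance term evaluated at
  the pooled correlation $\bar r$. The inter-index correlation it requires
  is always taken from the data. Z2* (which uses the individual
  correlations in the covariance term) differs only in that substitution;
  at the effect sizes relevant here the two agree to the second decimal, and
  Z1* is the variant with the better small-sample type-I behaviour, which
  the 2000-replicate null calibration in the test suite confirms.
* ANCOVA: `y ~ factor + covariate` with sum-to-zero contrasts and partial
  (Type III) F tests on $(1, n-3)$ df, matching the SPSS-style
  convention common in this literature. For this additive two-term model
  Type III coincides with drop-one nested-model F tests, which is how the
  oracle test verifies it.
* Bayes factors: the JZS default-prior t test. BF$_{10}$ is computed by
  adaptive quadrature of the noncentral-t likelihood over a Cauchy prior
  (scale 0.707) on the standardised effect size; one-sided alternatives use
  the half-Cauchy on the corresponding sign, so the two-sided factor equals
  the mean of the two one-sided factors (an identity the tests assert). The
  worked example — t = 0.47 with groups 32/24, one-tailed against the
  observed direction — evaluates to 0.2002, matching the printed rounded
  value 0.2 and an independent fine-grid quadrature oracle to better than
  three significant figures.
* PCA of the five user pairwise distances uses a centred, unscaled
  `prcomp`; a rank-one "overall scale" table loads uniformly on the first
  component.

## The synthetic cohort generator

No imaging data ship with the package; every downstream stage is exercised
on synthetic cohorts with *planted* representational geometries.

**Geometry templates.** A template is a condition set plus a target RDM of
squared distances. The control template encodes the natural-category
geometry (cosmetic near hands, active near tools, prosthesis types far
apart); the user template encodes the prosthesis cluster (the two prosthesis
types adjacent, displaced from hands and tools) with the hands–tools
distance unchanged. Both are built from explicit planar coordinates, so they
are embeddable by construction, and both have a hand-similarity contrast of
exactly zero — the generator plants the categorisation effect and an
embodiment null, the dissociation the index pair is designed to detect.
`embed_geometry()` realises a template as condition-mean voxel patterns via
classical MDS plus a random orthonormal rotation (so no voxel axis carries
structure); non-embeddable user-supplied RDMs are projected to the nearest
embeddable matrix by clipping negative Gram eigenvalues, with a warning.

**Noise.** Run-level noise and residual timeseries are drawn from a shared
squared-exponential covariance
$K_{ij} = \sigma^2 \exp(-(i-j)^2 / 2\ell^2)$ — a one-parameter spatially
smooth model that makes prewhitening non-trivial while keeping the noise
module honest (the residuals really do carry the covariance the whitening
estimates). Defaults are $\sigma^2 = 1$, $\ell = 2$ voxels, 4 runs, a
500-voxel ROI from a 1.2× candidate set, and 24 controls / 32 users. No empirical noise level
or between-run pattern reliability is available to constrain these
defaults, so $\sigma^2$ and $\ell$ are free choices, set to give clearly
structured group-mean RDMs at the design's run count.

**Geometry lives in noise-normalised space.** The planted means are coloured
by the noise-correlation square root, so that after (perfect) prewhitening
the pattern geometry reproduces the template. Without this convention,
whitening against spatially correlated noise distorts a Euclidean-planted
geometry direction-dependently, and the planted embodiment null would not
survive into the estimated RDMs. Defining the template in Mahalanobis units
is also the natural reading, since crossnobis estimates exactly those
distances.

**Usage coupling.** Per-user wear ratings and PAL items are sampled from a
latent usage propensity (primary-type probabilities follow the cohort
proportions: 40/25/16/16/3 percent for cosmetic / mechanical / myoelectric /
non-user / hybrid) and pushed through the *same* composite scoring chain as
real data, so the simulator exercises the usage module end to end. A user's
condition means are then interpolated linearly in pattern space between the
control and user templates with weight `usage_coupling` × (min–max
standardised usage score). Linear interpolation in pattern space (not in
distance space) guarantees every intermediate geometry is realisable.
Eligible users additionally receive an own-prosthesis condition displaced
from hands by a factor of 1.5 (in squared distance, at full weight) relative
to the control-matched generic prosthesis — the planted version of the
own-prosthesis effect.

**What the generator does not emulate.** No BOLD timeseries, hemodynamics,
motion, physiological artifacts, inter-subject anatomical variability, or
realistic localizer topography: betas and residuals are the atomic level.
Passing tests therefore demonstrate estimator correctness and pipeline
faithfulness under the planted model, not robustness to the full complexity
of real fMRI data.

## Numerical choices and degenerate inputs

* Gram eigenvalues below $10^{-8}$ of the spectral radius are treated as
  zero when embedding; genuinely negative ones trigger the projection
  warning.
* The whitener is the inverse symmetric square root via eigendecomposition;
  a non-positive-definite shrunk covariance raises an error rather than
  being silently regularised.
* Zero-variance voxels, runs with fewer than two residual timepoints,
  single-run designs, missing conditions, all-affected replacement sets,
  and zero control baselines all raise named errors at the module boundary.
* ROI tie-breaks, bootstrap resampling, and every simulation draw are
  seed-deterministic; identical configurations give bit-identical outputs.

## Problem sizes used by the checks

The test suite and the acceptance script run everything at reduced scale,
chosen so each check sits in a regime where its property is informative: the
fold-oracle equivalence enumerates all designs up to 4 runs × 4 conditions ×
5 voxels; null unbiasedness uses 1000 two-condition simulations; null-cohort
calibration uses 500 cohorts of 12 + 12 subjects (16 voxels, 2 runs);
planted-effect recovery uses 100 cohorts of 8 controls + 24 users with
40-voxel ROIs, 4 runs, and noise variance 0.5 (moderate noise, so estimator
attenuation of the planted usage correlation stays second-order); the
statistics layer is calibrated on 2000 null replicates per routine. The
noiseless-oracle comparison for the planted usage correlation uses 12
cohorts of 60 users at the same SNR.

## Known limitations

* The generator's noise is stationary along a voxel index; real fMRI noise
  covariance has richer structure (the estimator does not care, but the
  calibration evidence is for the stationary case).
* The Steiger comparison and the ANCOVA assume approximate normality of the
  indices; the planted generator satisfies this, heavy-tailed real data may
  not.
* Empirical group-level effect sizes (e.g., the group t values and usage
  correlations observed in real cohorts) depend on the underlying imaging
  data and are not reproducible from synthetic cohorts; the package verifies
  every computational component against oracles and reproduces the
  quantities that are derivable from printed inputs (the usage table and
  the Bayes-factor worked example).
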