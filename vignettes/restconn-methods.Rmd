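---
title: "Methods: voxelwise connectedness, network selectivity, and brain-behavior prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise connectedness, network selectivity, and brain-behavior prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restconn)
```

# The analysis

`restconn` implements a resting-state fMRI group analysis built around a
single voxel-level summary of global functional connectivity, the
**connectedness** of a voxel: the mean Pearson correlation of its BOLD time
series with every *other* gray-matter voxel's series, Fisher-z transformed
(`z = atanh(r)`). Group studies that use this summary ask whether a clinical
group shows diffusely altered coupling rather than alterations confined to a
prespecified network. The package covers the full chain:

1. **Motion QC** — mean frame-wise displacement (FD) per subject; strict
   exclusion at a threshold (default `fd < 0.30` mm/TR retains).
2. **Nuisance regression** — an ANATICOR-style model per voxel: 6 rigid-body
   motion parameters, a mean ventricle series, a *localized* white-matter
   average (15 mm sphere around each voxel), aCompCor principal-component
   series from noise tissue, optional precomputed physiological columns, and
   a Legendre polynomial baseline (order 4). Optional 6 mm FWHM Gaussian
   smoothing.
3. **Connectedness mapping** and a voxelwise group GLM
   (`value ~ intercept + group + FD`), two-sided t on `n - 3` df, BH-FDR.
4. **ROI definition** — dual threshold (`p < 1e-4` and `q < 0.05`) plus a
   connected-component cluster rule with an inclusive minimum extent
   (default 10 voxels, 6-neighbor faces adjacency).
5. **ROI-ROI matrices** — Fisher-z correlations of ROI mean series; per-pair
   group GLMs in one BH family over all `n(n-1)/2` pairs.
6. **Network selectivity** — average within-network minus average
   between-network voxel-pair correlation over a parcellation; group ANCOVA
   (effect-coded group, centered FD, interaction; Type-III F on 1 and
   `n - 4` df) and a partial correlation (df `n - 3`) between selectivity
   and mean ROI-pair connectivity.
7. **Brain-behavior prediction** — ROI-pair features reduced by PCA to the
   non-zero-eigenvalue components (`n - 1` for `n` subjects in general
   position), ridge regression (`K = 5`) with leave-one-out
   cross-validation, and a permutation test of the prediction correlation.

# Exact fast kernels

Connectedness is defined by an `O(N^2)` double loop over voxel pairs, which
is infeasible at realistic `N`. With each in-mask series standardized to
zero mean and unit norm (`u_i`), the package uses the exact identity

$$\frac{1}{N-1}\sum_{j \ne i} r_{ij} \;=\; \frac{u_i \cdot S - 1}{N-1},
\qquad S = \sum_j u_j ,$$

and analogous aggregate identities for the pooled selectivity averages
(within-network pair sums from `||S_k||^2`, cross-network sums from
`S_k \cdot S_l`). These are algebraic identities, not approximations; the
test suite requires agreement with the brute-force loops to `1e-10` on
instances up to 200 voxels.

Degenerate correlations (`|r| = 1` from collinear toy series) are clipped to
`1 - 1e-7` before `atanh` so maps stay finite; clip counts are recorded.
Constant series inside a mask are excluded from `N` with a warning rather
than poisoning their neighbors' means.

# Statistical conventions and the choices behind them

Several conventions are genuinely open in this style of analysis; the
package fixes a default and exposes the alternative behind a flag:

* **FD formula.** Rotations are converted to arc length on a 50 mm sphere
  (degrees to radians times 50); FD is the mean over frame transitions of
  the *Euclidean norm* of the six converted first differences. A
  sum-of-absolute-values variant (`method = "sum_abs"`) is provided; the
  Euclidean form is the default because it is the most common convention for
  a "mean framewise displacement in mm/TR" summary. FD is shift-invariant
  and degree-1 homogeneous in the parameter increments, which is what lets
  the motion simulator hit an FD target exactly by rescaling increments.
* **Selectivity scale and weighting.** Within/between averages pool every
  qualifying voxel pair with equal weight and average raw `r`
  (`scale = "r"`, `weighting = "pooled"`). Averaging Fisher-z values or
  weighting networks equally are defensible alternatives (`scale = "z"`,
  `weighting = "network"`); pooled raw-`r` is the default because
  "average within-network connectivity" most plainly denotes a pair-level
  mean, and selectivity differences are then expressed in correlation units.
* **Cluster adjacency.** Faces-only (6-neighbor) by default, with 18 and 26
  available. Faces-only is the most conservative standard choice and makes
  the inclusive 10-voxel minimum meaningful on small grids.
* **ANCOVA coding.** Effect-coded group and a centered covariate with
  Type-III tests keep the group "main effect" interpretable while the
  group-by-motion interaction is in the model. Without a covariate the
  group F reduces exactly to the squared pooled t (tested to `1e-8`).
* **Ridge details.** Predictors are standardized by training means/SDs
  within every cross-validation fold; coefficients solve
  `(Z'Z + K I) b = Z'(y - ybar)`; predictions apply the coefficients to the
  standardized held-out row *without an intercept*. `K = 0` reproduces OLS
  on the standardized design; `K -> Inf` shrinks all coefficients to zero.
* **Permutation p.** One-sided (`greater`) with the add-one correction,
  `p = (1 + #{r_b >= r_obs}) / (B + 1)`, so `p >= 1/(B+1)` and the test is
  exact under exchangeability. Shuffles are sampled with replacement from
  the permutation group under a user seed. PCA is computed once on all
  subjects — it is label-free, so permuting behavior does not require
  recomputing it; a leakage-free train-only PCA would be the variant to use
  if the reduction ever became label-dependent.
* **Rank-deficient nuisance designs** are fit through an SVD pseudo-inverse
  with relative tolerance `1e-10`, after naming the dependent columns in a
  warning; residuals remain exactly orthogonal to the design span, and
  residualization is idempotent.
* **Smoothing boundaries.** Zero padding with renormalization by the kernel
  mass inside the volume: uniform images stay uniform and small synthetic
  grids avoid edge attenuation. The ventricle mean is extracted before
  smoothing; the localized white-matter regressor after.

# The synthetic cohort generator

`simulate_cohort()` produces the ground-truth data every downstream claim is
tested against. Each voxel `i` of network `k` carries

$$x_i(t) = \sqrt{a}\, s_k(t) + \sqrt{g}\, h(t) + \sqrt{1 - a - g}\,
\varepsilon_i(t),$$

with unit-variance latent network series `s_k` (exchangeable correlation
`c` between networks), a global series `h`, and i.i.d. noise. The
population voxel-pair correlation is therefore `a + g` within a network and
`a c + g` between networks — closed forms the tests verify empirically at
2000 frames with tolerances frozen at three times the Monte-Carlo SD
measured over replicate runs (0.015 within, 0.010 between).

Defaults encode the study design the package targets: groups of 19 and 33
subjects, 123 frames at TR 2.5 s, a 17-network parcellation, group A with
elevated cross-network coupling and global signal
(`c = 0.50, g = 0.10` vs `c = 0.15, g = 0.02` at `a = 0.30`), giving a
population connectedness difference of about 0.18 r-units (above the 0.1
calibration floor) and lower selectivity in group A
(`a(1 - c)`: 0.15 vs 0.255). Group mean FD is 0.14 vs 0.06 mm/TR (subject
FDs drawn with SD half the group mean, floored at 0.01); motion tables are
Gaussian random walks rescaled so the realized FD matches the drawn target
exactly. White-matter and ventricle slabs carry independent noise plus a
0.2-share of the global series, so nuisance regression has real signal to
remove. Behavior is `beta * (w'f) + sigma * e` where `f` is the subject's
vector of network-pair Fisher-z connectivities and `w` is a unit-norm
weight vector drawn once per cohort and recorded in the metadata;
`beta = 1` with `sigma = 0.04` puts the signal SD (~0.092, measured in a
pilot at these defaults) above twice the noise SD. One seed drives the
whole cohort; per-subject sub-streams make generation order-independent.

Two spatial layouts are available: `"packed"` (default; one contiguous
gray-matter slab) and `"separated"` (each network in its own z-plane with
empty separator planes), the latter for tests that need a spatially
homogeneous effect to resolve into several distinct clusters.

**What the generator does not emulate:** hemodynamic response shapes,
anatomy, spatial autocorrelation of noise, physiological rhythms (physio
regressors enter only as precomputed columns), and — importantly —
*between-subject trait variance in connectivity*: all subjects of a group
share the same `(a, c, g)`. Passing tests therefore demonstrate the
pipeline's algebra, calibration, and sensitivity to group-level effects;
they do not demonstrate performance under realistic anatomy or individual
variation.

# A known limitation: behavioral power under this generator

Because group members share identical generative parameters, all
between-subject variance of the ROI-pair features is finite-length sampling
noise, with an essentially spherical subject-space covariance. A behavior
score tied to `w'f` then loads on subject-private noise directions that no
cross-validated model can learn from the remaining subjects: with 19
subjects and 18 PCA components, replicate runs show the LOOCV prediction
correlation for a *noiseless* `w'f` signal plateaus around 0.15 against a
permutation null SD of about 0.23, and detection rates stay near the
nominal type-I level regardless of `beta` or `sigma`. The permutation
test's *calibration* is unaffected (its null rejection rate sits at 5% and
its p-values are uniform); what is limited is attainable *power* under this
generative model. Real cohorts have stable individual differences in
connectivity, which is exactly the structure that makes the paper-style
prediction feasible; adding such trait variance to the generator would
change its stated contract (groups differing only through `a, c, g`, FD),
so the limitation is documented rather than papered over.

# Problem sizes used by the tests

The suite exercises kernels on toy grids up to 200 voxels (where brute-force
oracles are cheap and exact), generative recovery at 2000 frames, null
calibration with 200-500 replicates (voxelwise GLM, ANCOVA interaction,
permutation test at B = 500), effect recovery on 100 replicate 12-subject
micro-cohorts at 123 frames, and behavioral power on replicate 19-subject
cohorts at B = 1000. These sizes make the whole suite run in well under a
minute of kernel work plus a few minutes of replicate simulation on one
core while keeping every Monte-Carlo tolerance at 3 or more SDs.

# Degenerate inputs

* Empty ROI masks, empty tissue masks, single-level groups, constant
  covariates, and `|r| > 1` inputs are rejected with specific messages.
* Subjects with missing FD are reported as unevaluable, never silently
  dropped; missing ROI-pair values drop a subject for that pair only, with
  a warning.
* Zero suprathreshold voxels yield an empty ROI set, not an error.
* Zero-variance LOOCV predictions contribute a correlation of 0 (flagged),
  keeping the permutation count fixed.
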