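---
title: "Modeling daily growth as a reaction norm of soil moisture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling daily growth as a reaction norm of soil moisture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthrn)
```

## The problem

Time-series phenotyping of field trials (e.g. daily canopy area and height of
a few hundred crop accessions under several irrigation regimes) makes it
possible to ask *when* genotype-by-environment interaction happens during
growth, not just whether it shows up in the final phenotype. `growthrn`
models **daily growth** as a genotype- and growth-stage-specific **reaction
norm** of soil moisture,

$$\Delta y_{i,d} \;=\; y_{i,d} - y_{i,d-1} \;=\; \mathrm{SP}_{i,d}(s_{i,d-1}) + e_{i,d},
\qquad
\mathrm{SP}_{i,d}(s) \;=\; \sum_{q=1}^{Q} c_{q,i,d}\,\phi_q(s),$$

where $y_{i,d}$ is the trait of plot $i$ on day $d$ (days after sowing,
DAS), $s_{i,d-1}$ is the previous day's volumetric soil moisture, and
$\phi_q$ are B-spline basis functions on the observed moisture range. The
coefficients $c_{q,i,d}$ *are* the reaction norms: one curve per plot and
day, assumed to vary smoothly across genetically similar genotypes and
adjacent days.

Two daily-growth models are provided:

* **SP (spline / varying-coefficient)** — for each target (genotype $i$,
  day $d$), the coefficients minimize the locally weighted residual sum of
  squares
  $$\sum_{i'}\sum_{d'} G_{i,i'}\, k_0(d-d')\, e_{i',d'}^2,
  \qquad k_0(x) = \exp(-x^2/\lambda_0),$$
  a varying-coefficient regression: records from genetically similar
  genotypes ($G_{i,i'}$ large) and nearby days contribute most. Weights
  cannot be negative, so negative entries of a linear genomic kernel are
  clipped to zero (`clip_negative()`).
* **RF (random forest)** — a regression forest
  $y_{i,d} = \mathrm{RF}(y_{i,d-1},\, \mathbf g_i,\, s_{i,d-1},\, d)$ whose
  genotype representation $\mathbf g_i$ is the genotype's column of the
  genomic relationship matrix restricted to the training genotypes. Unlike
  SP it predicts the phenotype *level* and receives the previous level as a
  predictor, so it can express size-dependent growth.

Whole-season prediction is sequential: a mixed model predicts the
first-observation-day value, then each day's prediction feeds the next
(`predict_trajectory()`), never consulting observed phenotypes of the
validation plots.

## Surrounding pipeline

* **Height bias correction** (`estimate_daily_bias()`): remote-sensed canopy
  height carries a per-flight multiplicative bias; with manual heights
  $\mathrm{PH}$ on a plot subset, $\mathrm{CH}_{d,i} = b_d\,\mathrm{PH}_{d,i} + e_{d,i}$
  gives the through-origin least-squares $b_d = \sum \mathrm{PH}\cdot\mathrm{CH} / \sum \mathrm{PH}^2$,
  and corrected heights $\mathrm{CH}/b_d$. Days without ground truth get
  $b_d$ by linear interpolation (boundary days carry the nearest estimate) —
  the source protocol does not state a rule, so the simplest deterministic
  one is used. Bias correction precedes smoothing.
* **Growth-curve smoothing** (`smooth_growth_curve()`): cubic smoothing
  splines per plot, evaluated at every integer day. The penalty refers to
  `stats::smooth.spline`'s `lambda` on its standardized objective; defaults
  1e-4 (area-like) and 1e-3 (height-like). Penalty parameterizations differ
  across spline implementations, so these are calibrated defaults, not
  universal constants.
* **Soil-moisture interpolation** (`interpolate_moisture()`,
  `select_bandwidths()`, `densify_moisture()`): measurements exist only on
  an alternating subset of plots and days. Every plot x day value is a
  separable Gaussian-kernel weighted mean of measurements **from the same
  irrigation row** (each row has its own watering tube, so rows are treated
  as independent), with weights
  $\exp(-(l-l')^2/\lambda_s)\exp(-(d-d')^2/\lambda_t)$ over integer plot
  positions $l$ and days $d$. Bandwidths are selected by leave-one-out
  cross-validation (single-point exclusion) over a joint 17 x 17 log-spaced
  grid from 0.1 to 1000; ties break toward the smaller pair, spatial first
  (prefer locality). Being a convex combination, every interpolated value
  lies within the same-row measurement range.
* **Genomic kernels** (`build_linear_kernel()`, `build_gaussian_kernel()`):
  markers coded -1/0/1 are filtered (MAF >= 0.025, missing rate < 0.05,
  greedy LD pruning at r^2 >= 0.95 in a 50-marker window — the LD metric and
  window are implementation choices; only the threshold is prescribed
  upstream). The linear kernel uses the VanRaden normalization
  $X_c X_c^\top / (2\sum_k p_k(1-p_k))$, matching standard GBLUP software;
  the Gaussian kernel is $\exp(-\lVert x_i - x_j\rVert^2/\lambda_g)$ with
  $\lambda_g = 10^5$ by default (the value a 1e5..1e7 CV search selects on
  dense genome-wide data).
* **Benchmarks** (`fit_gblup()`, `run_gp_gpg()`): single-trait genomic
  prediction per observation day — GP on levels, GPG on daily increments
  accumulated from the first-day prediction. The mixed models are solved by
  REML (profile likelihood on the eigenbasis of $ZKZ^\top$, one bounded 1-D
  optimization) followed by closed-form mixed-model equations. This
  deterministic solver replaces sampling-based machinery: for these Gaussian
  models the REML/BLUP solution is the posterior mode the samplers target,
  and exactness against a fixed-ratio Henderson-equations oracle is part of
  the test suite. Equivalence to any particular MCMC run is not claimed.

## Cross-validation schemes

`make_cv_plan()` builds three schemes over genotypes and environments
(an environment = treatment x year):

* **CV-G** — 5-fold genotype partition, repeated (10 by default); the
  first-day model is a per-environment kernel GBLUP.
* **CV-E** — leave-one-environment-out; all-environment model with fixed
  environment effects and an *identity* genotype covariance (test genotypes
  were seen in other environments). The held-out environment has no fixed
  -effect estimate, so predictions fall back to the mean of estimated
  environment effects — some choice is forced; this one is neutral.
* **CV-GE** — every (fold, environment) pair, training on other folds x
  other environments only; kernel GBLUP with environment fixed effects.
  Training/test disjointness (including no shared genotype or environment
  for CV-GE) is asserted on every split.

Accuracy is the Pearson correlation between predicted and smoothed values
per (environment, day) cell across the cell's plots, averaged over repeats
before any tallying; zero-variance cells are excluded, not zero-filled.
`compare_models()` counts strict wins cell by cell, with ties reported
separately.

## The synthetic field trial

`simulate_trial()` generates the complete data world the pipeline consumes,
with known ground truth, emulating a drought trial of a structured soybean
-like diversity panel:

* **Genotypes** — biallelic SNPs for a panel of `n_subpops` subpopulations
  (default 8) whose marker frequencies diverge from a uniform-MAF ancestral
  pool under the Balding-Nichols model with $F_{ST} = 0.3$. The resulting
  kernel has the within-group relatedness blocks that make genomic
  prediction of unseen genotypes informative — with an unstructured panel
  the off-diagonals vanish and every cross-genotype scheme collapses to
  zero accuracy by construction. Markers whose empirical MAF falls below
  0.025 are redrawn, so the matrix behaves like post-filter data. At the
  packaged 40-genotype scale, cross-genotype accuracy rests on a handful
  of realized family means, so its *level* varies considerably between
  simulated panels; the packaged experiments therefore fix their seeds,
  and single-run accuracy levels should not be over-read.
* **Soil moisture** — deterministic treatment patterns (well-watered
  set-point 6 %v/v; exponential dry-down to a floor of 2 %v/v with a 6-day
  time constant, the fast drainage sandy soils show; exactly periodic
  5-on/5-off and 10-on/10-off cycles built
  from anchored piecewise exponentials), plus a smooth along-row spatial
  effect (SD 0.3) and AR(1) daily noise (SD 0.3, lag correlation 0.6).
  The set-points are configurable conventions, not claims about any real
  field: published values for comparable sandy-soil trials put the observed
  range at roughly 2.5-4 %v/v in dry spells.
* **Reaction norms** — each coefficient $c_{q,i,d}$ is a seasonal mean curve
  (bell-shaped envelope peaking at 40 DAS, width 18 d, maximum 1.8 trait
  units/day at high moisture, response rising from 0.25 to 1 across the
  basis) plus deviations with separable covariance: genomic kernel across
  genotypes x squared-exponential (length scale 10 d) across days,
  partitioned by `h2_coef` (default 0.7) into a genetic and a common
  day-smooth part. Deviations are scaled by the seasonal envelope so
  growth-rate variance tracks the growth rate itself, as it does in real
  canopy series. The separable form mirrors the estimator's smoothness
  assumption deliberately, so parameter recovery is well-posed.
* **Trial layout and observation** — one plot per genotype per environment,
  rows of 20 plots; initial size log-normal (median 8, log-SD 0.3) with
  heritable log-size (`h2_init = 0.8`, kernel-structured) — the first
  observation day reflects two weeks of genetically variable growth, so it
  must carry genetic signal; a persistent per-plot growth-rate effect
  (SD 0.15 units/day) emulating soil/micro-environment heterogeneity;
  Gaussian daily growth noise (SD 0.25 units/day); per-day multiplicative
  observation bias drawn from [0.9, 1.1]; additive observation noise
  (SD 1 unit); soil moisture observed on every other plot position, split
  into two groups measured on alternating days; manual heights (noise-free
  realized sizes) on 8 evenly spaced plots per environment, daily.
* **Planted response classes** — optionally three discrete low-moisture
  response classes (offsets -1.2/0/+1.2 units/day on the lowest-moisture
  basis coefficient inside a Gaussian window centred at 20 DAS, width 8 d),
  emulating discrete early-stage drought-response types. Classes are
  heritable and follow the panel's family structure (terciles of a
  kernel-smoothed polygenic score), because a response type that cuts
  across genetic groups cannot be preserved by any kernel-weighted
  estimator — nor, for that matter, predicted for unseen genotypes. The
  separation is chosen so adjacent classes sit several within-class
  genetic SDs apart at the probe point (20 DAS, 2.5 %v/v): closer classes
  are indistinguishable even from the true coefficients, which would make
  class-recovery checks meaningless.

What the generator does **not** emulate: image-level artifacts (segmentation
error structure, occlusion), linkage disequilibrium decay along chromosomes
(markers are exchangeable), phenology differences among genotypes (all share
one seasonal envelope), weather covariates other than soil moisture, and
non-Gaussian measurement error. Tests passing on this world therefore
validate the estimators' correctness and the pipeline's logic, not
performance on any real dataset.

## Numerical choices

* The varying-coefficient solve adds a ridge `1e-6 * sum(w) * var(dy)` to
  the normal equations by default for numerical stability; plain weighted
  least squares is recovered with `ridge = 0`, and the oracle-equivalence
  tests run at `ridge = 0` on well-conditioned fixtures.
* `fit_all()` exploits the separable weight structure (genotype part x day
  part): per-day cross-product blocks are formed once per genotype and
  recombined per target day, giving results identical to the naive
  per-target solve (asserted to 1e-8) at a fraction of the cost.
* Moisture outside the basis support is clamped to the boundary and
  flagged — reaction-norm estimates at the periphery of the observed
  moisture range are unstable, and extrapolating the polynomial tails would
  be worse.
* B-spline bases: `Q` functions with cubic degree (reduced to `Q - 1` when
  `Q <= 3`), boundary knots at the observed moisture range, interior knots
  at equally spaced quantiles; with the intercept retained the basis is a
  partition of unity.
* Tercile grouping of reaction norms at a probe point breaks ties stably by
  genotype id.
* REML optimizes the log variance ratio on [-8, 8] * ln 10; a fixed
  `var_ratio` skips optimization entirely (used by the oracle tests).
* All randomness flows from the configuration seed through fixed offsets
  per stage, so identical configurations reproduce every table bitwise.

## Hyperparameters

| Parameter | Meaning | Default / grid |
|---|---|---|
| `Q` | B-spline basis size (moisture) | 3; grid \{3, 4, 5\} |
| `lambda0` | day-kernel bandwidth (days^2 scale) | 10; grid \{10, 30, 50, 70\} |
| kernel | weight/covariance matrix | linear (clipped) or Gaussian |
| `lambda_g` | Gaussian kernel bandwidth | 1e5 (1e5..1e7 range) |
| `mtry` | RF predictors per split | grid \{5, 10, 15, 20, 25, 30\} |
| `n_trees` | RF ensemble size | 500 |
| smoothing `lambda` | curve interpolation penalty | 1e-4 area, 1e-3 height |
| `lambda_s`, `lambda_t` | moisture interpolation bandwidths | LOOCV over 17 log-spaced values 0.1..1000 |

The reaction-norm tabulation mode (`extract_rn_curves()`) uses
`lambda0 = 10`, the smallest grid value, because larger bandwidths smooth
away the stage-to-stage variation the curves are meant to display.

## Problem sizes used in validation

The packaged experiments run on a 40-genotype x 4-treatment x 50-day trial
(160 plots): large enough that kernel structure, seasonal dynamics, and all
three CV schemes are exercised, small enough to iterate on. Cross-validated
experiments use 5 folds x 2 repeats. These sizes are the package's own
validation conditions; nothing prevents running the same functions on a
198-genotype, 8-environment dataset.

## Known limitations

* The varying-coefficient weights require a non-negative kernel; clipping
  negative linear-kernel entries changes the implied covariance, and the
  validity of that treatment is an open question inherited from the method.
* Reaction norms for a genotype with no moisture variation near a day are
  determined mostly by the kernel-weighted population mean there.
* The RF model cannot extrapolate beyond the training response range;
  early-season predictions for traits that start near zero are
  systematically coarse.
* CV-E's fallback fixed effect (mean of training environments) makes its
  level predictions only as good as the environments are exchangeable.
* Sequential prediction has no error-correction mechanism; a state-space
  formulation would be the natural extension.
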