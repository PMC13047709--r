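---
title: "Methods: ensemble SDM, habitat accounting and climate-anomaly analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble SDM, habitat accounting and climate-anomaly analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmflow)
```

`sdmflow` implements a presence/pseudo-absence ensemble species
distribution model (SDM) and the habitat accounting that usually follows
it. This vignette is the package's methodological record: the model and its
assumptions, every tunable that matters, the numerical decisions, what the
synthetic test system does and does not demonstrate, and the known
limitations.

## The modelling problem and its assumptions

The data are presence-only records plus gridded environmental layers. The
standard workaround for missing absences is the presence/background
design: contrast the environment at presences against a random background
sample ("pseudo-absences"), fit probabilistic classifiers, and read their
output as relative habitat suitability. That carries the usual
assumptions, which `sdmflow` inherits rather than removes:

* **Niche stationarity** — the species–environment relationship estimated
  from current data is assumed to transfer to other periods. The MESS
  module exists precisely to flag where this assumption is being
  stretched (cells outside the training environmental range).
* **Sampling adequacy** — occurrences are treated, after thinning, as an
  unbiased sample of occupied environments. Spatially structured survey
  bias is not modelled.
* **Pseudo-absences as absences** — background points enter AUC/TSS as
  absences. Metrics are therefore relative discriminations, not absolute
  error rates.

## Pipeline stages and their tunables

| Stage | Parameter (default) | Meaning |
|---|---|---|
| Thinning | `radius_km = 1` | minimum allowed pairwise distance (km; map units on abstract grids) |
| Pseudo-absences | `n_points = 1000`, `n_sets = 2` | background sample size, replicated sets |
| Weighting | `prevalence = 0.5` | class-weight balance; 0.5 equalizes total presence and background weight |
| Splits | `train_frac = 0.75`, `n_reps = 10` | stratified train/test fraction and repetitions |
| Screening | `c_min = 0.5` (%), `r_max = 0.8` | minimum contribution; collinearity cutoff on absolute Pearson r |
| Maxent tuning | RM `0.5–4 by 0.5`, FC `{L, LQ, LQH, H, LQHP, LQHPT}` | 48-point regularization-by-features grid, selected by AICc |
| Ensemble gate | `auc_min = 0.90`, `tss_min = 0.80` | strict lower bounds on an algorithm's mean test skill |
| Grading | breaks `0.3, 0.6, 0.85` | unsuitable/low/moderate/high breakpoints on suitability P |
| Binarization | `cut = 0.3` | presence iff P > 0.3 |
| Areas | constant `1 km²`/cell, or latitude-cosine | cell-area model for all accounting |

Thinning is order-dependent by construction; the record order is shuffled
by a logged seed, and the retained set always satisfies the pairwise
minimum-distance property. Great-circle (haversine) distance is the
default for geographic coordinates; Euclidean distance serves abstract
grids where the "kilometre" is the map unit.

Contribution rates are prediction-permutation importances: for variable
*j*, one minus the Pearson correlation between reference predictions and
predictions with column *j* permuted, averaged over `n_shuffles = 5`
shuffles, clipped at zero, and normalized to percentages. They are
computed from a preliminary boosted-trees fit on all candidate variables
— the de-facto standard in ensemble-SDM practice, and self-contained.
Correlations for the collinearity rule are computed over all valid cells
of the calibration stack (not just the sampled points), which stabilizes
them. Two boundary choices matter and are deliberate: a contribution of
exactly 0.5 % is *retained* (the rule drops strictly-below values, which
keeps the two screening rules consistent with each other at the
boundary), and ties in contribution are broken alphabetically so
screening is deterministic.

## The native maxent-style learner

The package's own presence/background learner mirrors the maxent model
family: min–max scale each variable to [0, 1] by background statistics
(projection values are clamped into that range); expand features —
linear `x`, quadratic `x²`, products `x_j·x_k`, forward/reverse hinges
`max(0, (x−k)/(1−k))`, `max(0, (k−x)/k)`, and step indicators `x > k` at
evenly spaced interior knots (50 per variable by default); then fit an
L1-penalized logistic presence-vs-background regression. The penalty for
a feature is `RM × base(class)`, with documented base constants
(linear/quadratic/product 0.05, hinge 0.5, threshold 1.0) and overall
strength scaled by `1/sqrt(n_presence)` — simple classes are cheap,
data-hungry classes expensive, and everything relaxes as presences
accumulate. The output is the plain logistic response; no cloglog
transform (downstream thresholds operate on [0, 1] regardless, so the
choice only shifts the threshold, not the ordering).

Model selection follows the information-theoretic convention: the raw
exponential scores are normalized over the presence + background sample,
the log-likelihood is summed at presences, `k` counts nonzero
coefficients, and `AICc = 2k − 2lnL + 2k(k+1)/(n−k−1)`. Combinations
with `n − k − 1 ≤ 0` are marked invalid and never chosen. The selected
combination has `delta AICc = 0`; ties break by higher held-out AUC, then
smaller RM, then shorter FC string — fully deterministic. The
`delta AICc < 2` set is reported as "reliable".

`MAXENT` and `MAXNET` in the registry are two configurations of this one
core: a default-feature configuration and the tuned one. Of the remaining
registry names, GLM/GAM/CTA/RF/GBM/ANN/XGBOOST are fitted through the
standard R modelling packages (`stats`, `mgcv` penalized-spline logistic,
`rpart`, `randomForest`, `xgboost` with conservative gbm-like defaults
for `GBM` and its own defaults for `XGBOOST`, `nnet`), all behind the
same predict-in-[0, 1] contract; `FDA` and `MARS` have no backing
implementation here and always enter the member table as "failed"
records — deliberately exercised in the tests, because a robust protocol
must tolerate member failure rather than abort.

## Evaluation, gating and the committee

AUC is the rank-based (Mann–Whitney) statistic with half-credit for
ties; TSS is maximized exactly over the data-driven candidate thresholds
(midpoints of consecutive distinct scores plus 0 and 1 — a fixed grid
cannot do better, and the smallest maximizing threshold is reported for
determinism). Test folds are scored unweighted; the prevalence weights
affect fitting only.

The gate operates at algorithm level — an algorithm's mean AUC and mean
TSS over successful runs must strictly exceed 0.90 and 0.80 — because
skill summaries in this workflow conventionally name whole algorithms.
A run-level gate is available. Members are weighted proportionally to
their test TSS (no decay exponent; TSS rather than AUC because the final
products are threshold-based maps, and TSS measures exactly the
thresholded skill). Weighting by AUC is a configuration switch.

## Habitat accounting

Grades use half-open intervals with boundaries in the lower class
(P = 0.3 is unsuitable; P = 0.85 is moderate). Binarization is strict
(P = 0.3 is absence) — forced by consistency with the grading rule, which
places 0.3 in the unsuitable class. Change analysis defaults to the
moderate + high classes (grade ≥ 3); a configuration flag switches to all
suitable classes (P > 0.3). Expansion and contraction rates are
percentages of the previous-period suitable area, which the change
categories reconstruct identically as `retained + loss` — this identity
is asserted in the tests and holds exactly, full stop. Areas are summed
at full precision and only rounded (2 decimals, units of 10⁴ km²) in the
written report tables.

## MESS and the most-dissimilar variable

For one variable with reference sample of size *n* and query value *p*,
let `f` be the percentage of reference values strictly below *p*. The
similarity is `100(p−min)/(max−min)` when `f = 0`, `2f` when
`0 < f ≤ 50`, `2(100−f)` when `50 ≤ f < 100`, and `100(max−p)/(max−min)`
when `f = 100`: 100 exactly at the median, 0 at the range limits,
negative and unbounded outside. The cell's MESS value is the minimum over
the screened variables; the variable attaining it (smallest index on
ties) is the most-dissimilar variable (MoD). The reference sample is the
predictor matrix at the calibration points (presences + the first
pseudo-absence set) — the "training data" reading; reporting bands are
extreme (S < 0), anomalous (0 ≤ S < 10) and similar (S ≥ 10). Degenerate
(constant) reference variables are a flagged error rather than silently
producing infinities.

## The synthetic study system

`simulate_landscape()` generates the default test system: a 120 × 120
abstract grid of 1 km² cells with 12 layers, each a standardized
Gaussian-smoothed random field (kernel sd 6 cells); two engineered
near-duplicate pairs (`env11 ~ env01`, `env12 ~ env04`, target r = 0.95)
to exercise collinearity screening; a logistic truth surface on three
active layers (β = 14, −10, 8 with a −5 quadratic on the first,
intercept −18); 300 presences drawn proportionally to the truth with
sub-cell jitter; and two deterministic future shifts — a mild shift of
the dominant layer toward its optimum, and an extreme +8 sd shift of
`env01` *and* its near-duplicate (correlated layers move together) that
pushes every cell outside the reference range.

The truth coefficients were frozen once, on a design argument: sampling
presences proportionally to suitability caps the achievable AUC at
`1 − f/2`, with `f` the suitable fraction of the landscape, so a niche
occupying roughly 6–14 % of the domain (matching the rarity typical of a
narrowly distributed crop) is what makes the published-style member gate
(AUC > 0.90, TSS > 0.80) attainable at all. A diffuse niche would make
the gate unreachable by *any* learner — a property of the sampling
design, not of the learners.

What the synthetic system emulates: spatial smoothness, inter-layer
correlation, a low-prevalence species with a partly unimodal response,
range-expanding and range-exceeding scenario shifts. What it does not:
real bioclimatic covariance structure, survey bias, observation error in
coordinates, and irregular study-area masks. Passing tests therefore
demonstrate that the machinery is correct and recovers a known truth
under clean conditions — not that any particular real-world prediction
is accurate.

Default problem sizes in the test-suite (60–120 grid cells a side,
150–300 presences, 2 × 200–500 pseudo-absences, 2–5 repetitions, 5–10
knots for hinge/threshold features in tuning tests) were chosen to keep
the full suite in the low minutes while preserving every structural
property of the full protocol; the pipeline defaults themselves are the
full protocol numbers (2 × 1000 pseudo-absences, 10 repetitions, 50
knots, the complete 48-point tuning grid).

## Numerical choices and degenerate inputs

* Grid alignment uses an absolute tolerance of 1e-9 on all six geometry
  fields; ASCII rasters are written with 6 significant digits and
  round-trip bit-identically at that precision.
* Points map to cells by `floor((x − x₀)/cell)` with half-open
  intervals; cell (1, 1) is the top-left. Out-of-bounds and masked
  points are flagged and excluded with a logged count, never an error.
* Train-fold size is `round(train_frac · n)` per class, reduced if a
  test fold would be empty; datasets with fewer than 4 presences are
  refused.
* Zero-variance predictors: correlations are reported as 0 with a
  warning (screening), features are skipped with a warning (maxnet), and
  MESS raises a flagged error.
* glmnet requires at least two design columns, so single-feature maxnet
  designs are padded with a zero dummy column that can never earn a
  coefficient.
* All stochastic stages derive their seeds from one master seed by a
  documented hash of the stage label, so any stage can be reproduced in
  isolation and a full rerun is bit-identical.
* Random-forest members are fitted unweighted (the backend has no
  per-observation weights); all other weight-capable learners honour the
  prevalence weights.
* `smooth_field()` standardizes each layer after smoothing, so
  increasing smoothness flattens spatial roughness but never the
  marginal variance; tests assert the roughness ordering.

## Known limitations

* No reprojection or resampling: stacks must arrive aligned (the
  synthetic module always produces aligned stacks). Raster I/O is ESRI
  ASCII; georeferenced binary formats are out of scope.
* FDA and MARS are registry names without backends, by design recorded
  as failed members.
* MESS's MoD is the most-dissimilar variable, not a model-sensitivity
  "limiting factor" analysis.
* Pseudo-absence evaluation means AUC/TSS compare presences against
  background, with the usual interpretive caveats.
* The ensemble is a weighted mean; median or confidence-envelope
  committees are not implemented.
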