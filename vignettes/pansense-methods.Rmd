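---
title: "Swarm-optimized feature selection for pan-genome sensory prediction: models, parameters and design choices"
author: "pansense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-optimized feature selection for pan-genome sensory prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pansense)
```

This vignette is the package's account of its method: the model and its
assumptions, the tunable parameters, what the synthetic-data generator does
and does not emulate, the numerical choices, and the design decisions made
where the design was genuinely open.

## The prediction problem

The package predicts real-valued sensory phenotypes of fermented milk —
eight electronic-tongue taste channels and ten electronic-nose odor sensors —
from a strain's pan-genome profile: a binary samples × features matrix
combining three feature classes, SNPs, gene presence/absence, and
intergenic-region (IGR) variants.  The defining difficulty is extreme
dimensionality imbalance: on the order of 10² strains against 10⁵ binary
features.  Plain regularized regression on the raw matrix is unstable and
uninterpretable at that ratio, so the method is organized entirely around
feature selection.

The three class matrices are column-concatenated into one feature space with
class-prefixed identifiers (`SNP_`, `GENE_`, `IGR_`).  This treats the
classes as one pool — which is also what makes shared-feature counting across
phenotypes meaningful — rather than modeling them separately.

## The four-stage pipeline

Selection proceeds through four serialized stages; each stage only removes
(or, for PCA, recombines) features, so survivor sets are nested.

**Variance threshold (VT).**  Feature `j` is kept iff its *population*
variance is at least the threshold `t`.  The search range for `t` is
`[0, 10⁻⁴]`: a Bernoulli(p) feature has variance `p(1−p)`, so this range
removes only features that are essentially constant in the panel
(`p ≲ 10⁻⁴`).  The filter deliberately operates on the raw 0/1 values —
after standardization every non-constant feature would have variance 1 and
the threshold would be meaningless.

**Univariate F selection (UFS).**  Each feature is scored by the
simple-regression F statistic `F_j = r_j²(n−2)/(1−r_j²)`, `r_j` the Pearson
correlation with the phenotype.  Constant features score 0; a perfectly
correlated feature scores `+Inf`; score ties break toward the lower feature
index so selection is deterministic.  "Keep the top `percentile` percent" is
made integral as `max(1, ceiling(p · percentile/100))`, which keeps all
features at 100 and at least one feature always.

**Recursive feature elimination with cross-validation (RFECV).**  Features
are standardized (zero mean, unit population variance; constant columns
become all-zero), ridge regression with penalty `λ = 1` and an unpenalized
intercept is fitted, and the `step` features with smallest absolute
coefficients are removed — never dropping below `min_features`.  At every
visited feature count the mean 10-fold CV score is recorded (error metrics
negated so all four criteria are maximized); the returned feature set is the
count with the best mean CV score, ties resolved toward fewer features
(parsimony).  Ridge is the estimator throughout — it is fast in high
dimensions, handles the heavy multicollinearity of pan-genome data through
L2 shrinkage, and its coefficients directly express feature influence.

**PCA.**  The selected standardized features are mean-centered and projected
onto the top `n_components` right singular vectors.  Loadings are
orthonormal and explained variance is non-increasing.  Whether to compute
PCA on standardized or raw selected features was an open choice; the package
uses covariance PCA *on the standardized selection* so that the later
importance back-projection lives on the same scale as the ridge fits.  A
final ridge model (again λ = 1) on the component scores produces
predictions.

`λ` is fixed at 1.0 in all three ridge roles (elimination, fitness, final
model).  Tuning it would enlarge the optimizer's search space beyond its six
standard dimensions; fixing it keeps runs comparable.

## The Dung Beetle Optimizer

The six pipeline parameters — threshold (continuous), percentile, step,
minimum feature count, CV scoring criterion (categorical: R², MSE, RMSE,
MAE), and component count — are tuned by the Dung Beetle Optimizer, a
population metaheuristic with four behavioral roles.  The configuration is
50 beetles split 20 % rolling / 40 % foraging / 20 % stealing / 20 %
reproducing, stopping after 100 iterations; role membership is a static
index-block partition.

The update rules follow the canonical published formulation of the
algorithm: ball-rolling `x ← x + α·k·x_prev + b·|x − x_worst|` with
`α ∈ {−1, +1}` random, `k = 0.1`, `b = 0.3`; with probability 0.1 a roller
"dances" instead, `x ← x + tan(θ)|x − x_prev|`, `θ` uniform on `(0, π)`
excluding `π/2`; brood balls are sampled inside the region
`[max(x*(1−R), lb), min(x*(1+R), ub)]` that shrinks around the
iteration-local best `x*` with `R = 1 − t/T`; foragers move relative to the
same shrinking region around the *global* best; thieves contract toward the
global best, `x ← x_best + S·g·(|x − x*| + |x − x_best|)`, `g ~ N(0,1)`,
`S = 0.5`.  All positions are clamped into bounds after every update.

The population itself stays continuous; mixed variable types are handled at
evaluation time by decoding — integers round half-up then clamp,
categoricals map by floor into the category list.  Evaluations that error or
return non-finite values (for example a component count exceeding the
surviving feature count) score `−Inf` and the search continues; the
incumbent best is never replaced by a worse point, so the best-so-far trace
is monotone.

```{r}
space <- pipeline_param_space(n_samples = 194)
config <- dbo_config(space$bounds, dim_kinds = space$dim_kinds,
                     categories = space$categories, seed = 1)
```

## Fitness, caching, and the compiled elimination core

The fitness of a decoded parameter point is the mean 10-fold CV score of the
final ridge model on the component scores, with one shuffled fold assignment
per run (a fixed fold seed shared between fitness evaluation and final
evaluation, so the optimizer optimizes exactly the quantity later reported).

Two implementation facts make the search tractable at realistic problem
sizes, without changing any semantics:

* **Dual formulation and the block-CV identity.**  For ridge,
  `β = X'(XX' + λI)⁻¹y` exactly, so the elimination path runs on the n × n
  gram matrix; removing `step` features is a rank-`step` downdate, and the
  maintained inverse is updated by Sherman–Morrison–Woodbury (refreshed
  periodically from the exactly maintained gram so floating-point drift
  stays at rounding level).  Out-of-fold predictions at every feature count
  come from the exact cross-validation identity for penalized-least-squares
  smoothers: with hat matrix `H`, `I − H = λ(K + λI)⁻¹C` (`C` the centering
  projector of the unpenalized intercept), and the predictions of fold `F`
  from a model fitted without fold `F` are
  `pred_F = y_F − [(I−H)_FF]⁻¹((I−H)y)_F`.  The test suite verifies this
  against an explicit per-fold solver (agreement ~10⁻¹⁴) and against a
  literal pure-R elimination oracle.

* **Structured memoization.**  During optimization, results are cached at
  the level where they are actually determined: the VT survivor set by the
  threshold, the UFS mask by (survivors, percentile), the elimination path
  and its out-of-fold predictions by (survivors, percentile, step) — the
  floor only truncates the path (within each round features are dropped in
  increasing |coefficient| order, so survivors at any count are the
  complement of a prefix of the elimination order), the scoring criterion
  re-scores cached predictions, and the PCA head reuses a cached SVD.  Spot
  checks in the suite confirm the memoized evaluator is bit-identical to
  running the stages directly.

## Model comparison

Ten regression families are compared on the selected representation under
the same 10-fold scheme, with per-fold metrics (R², MAE, MSE, RMSE) averaged
across folds; the best model per phenotype maximizes mean R², ties breaking
to the lexicographically first name.  Hyperparameters are frozen library
defaults kept in one registry, because the method's contribution is the
selection pipeline, not model tuning: ridge (λ = 1, closed form), lasso and
elastic net (glmnet, fixed λ = 0.01, α = 1 / 0.5), ε-SVR with RBF kernel
(e1071), random forest (ranger, 100 trees), least-squares gradient boosting
over rpart stumps (100 trees, depth 3, shrinkage 0.1 — written in-package
since no dedicated gradient-boosting package is available here), decision
tree (rpart), XGBoost (100 rounds), k-NN (caret, k = 5), and a
single-hidden-layer neural network (64 tanh units).  The neural network is
fitted by an in-package full-batch Adam loop rather than a BFGS-based
fitter: BFGS cost grows quadratically with the weight count, which is
prohibitive at the component dimensions the pipeline produces, while the
architecture itself (one hidden layer of 64 units, fixed seed, fixed epoch
cap) is unchanged.

Folds too small to define R² (leave-one-out) report `NA` for that metric
rather than failing; the error metrics are always defined.

## Importance back-projection

With loadings `L` (selected features × components) and ridge coefficients
`β`, each surviving original feature receives the signed total contribution
`c = Lβ`.  Because `scores = X_c L`, the contribution vector reproduces the
component-space prediction exactly (`scores·β = X_c·c`), which the suite
checks both algebraically and against finite-difference slopes of the fitted
predictor.  Contributions are reported on the standardized-feature scale
used by the pipeline fits — magnitudes are then comparable across features
with different allele frequencies — and ranking uses |c| with the sign
retained, unnormalized.

## Sensory analytics

Phenotype correlation uses Spearman's rank correlation on mid-ranks;
distribution summaries use type-7 quartiles with 1.5 × IQR whiskers.
"Shared features" between two phenotypes are counted at the post-RFECV stage
— principal components are not original features, so counting after PCA
would be meaningless — and the association between |phenotype correlation|
and shared-feature count over all unordered pairs is itself summarized by a
Spearman ρ.  When shared counts are constant across pairs the association is
undefined and reported as `NA` with an explanation rather than a number.

## The synthetic-data generator

The generator stands in for the request-only 194-strain panel and is
first-class, tested code.  It emulates exactly the statistical structure the
analyses rely on:

* binary features in the three classes, each feature an independent
  Bernoulli with frequency drawn uniformly from `presence_prob_range`
  (default (0.1, 0.9) — wide enough to cover common and rare variants while
  keeping every feature clearly polymorphic);
* phenotypes that are sparse additive signals: `y = Σ w_j g_j + ε`, default
  20 causal features per phenotype, weights of magnitude Uniform(0.5, 1.5)
  with random sign (mixed signs exercise the signed importance
  propagation);
* noise calibrated to a target signal fraction `Var(signal)/Var(y)`
  (default 0.9, matching the high attainable predictive performance the
  method is designed to demonstrate) against the *realized* genetic variance
  of the simulated panel;
* planted causal overlap: consecutive phenotype pairs share 75 % / 25 % /
  0 % of their causal features (recycled across the four pairs of the
  default eight phenotypes).  A feature shared by two phenotypes carries the
  same weight in both — consistent pleiotropy — which is the mechanism that
  makes causal overlap induce phenotype correlation and hence gives the
  shared-feature analysis something real to detect.  Explicit
  `phenotype_specs` allow arbitrary overlap designs.

Default dimensions are desk-scale: 194 samples and 5,000 features split
2500/1500/1000 across SNP/GENE/IGR, preserving roughly the 58/26/16 %
class proportions of real pan-genome matrices while keeping a full
optimizer run in minutes.  What the generator does *not* emulate — and what
passing tests therefore do not establish about real data — is linkage
structure (features are independent; real variants are correlated along the
genome), population structure among strains, epistasis or any non-additive
genotype–phenotype map, and measurement artifacts of the sensor instruments.
On real panels the selection stages face correlated features, where
"recovering the causal feature" and "recovering a linked proxy" are not
distinguishable; the causal-recovery metrics reported here are meaningful
precisely because independence makes them unambiguous.

## Numerical choices and degenerate inputs

* Population (divide-by-n) variance everywhere a variance threshold or
  standardization is involved; sample variance only inside PCA's explained
  variance (inherited from the SVD convention).
* Zero-variance columns standardize to all-zero rather than NaN; they score
  0 in UFS and are eliminated first in RFECV (ties break by feature index).
* A zero-variance phenotype makes R² undefined: fitness returns `−Inf`;
  metric computation raises an error.
* The fold assignment shuffles once per seed; fold sizes differ by at most
  one; every sample appears in exactly one test fold.
* RFECV best-count ties resolve toward fewer features; UFS score ties toward
  the lower feature index; best-model ties toward the lexicographically
  first name.  Every tie-break is deterministic, which is what makes the
  end-to-end workflow reproduce byte-identically under one seed.
* The maintained inverse in the compiled core is refreshed from the exactly
  maintained gram every 64 elimination rounds.

## Problem sizes used in the test suite

The suite exercises the method at deliberately chosen scales: oracle
equivalence on 30 × 40 panels; planted recovery at n = 200, p = 5000 with 20
causal features, signal fraction 0.9 and a reduced optimizer budget (10
beetles, 20 iterations, medians over 5 seeds); the overlap-correlation trend
on four phenotypes with planted overlaps {0, 10, 30} of 40 causal features;
and full workflow reproducibility on a 60 × 400 panel.  These sizes keep a
complete run of the suite in a few minutes on one CPU while leaving every
stage genuinely high-dimensional relative to the sample count.

## Known limitations

* Feature independence in the generator (above) is the strongest
  simplification; a correlated-block option is a non-goal.
* The ridge penalty is fixed, not tuned; phenotypes whose genetic
  architecture departs strongly from sparse additivity would warrant a
  different estimator inside RFECV.
* The DBO update equations and constants are taken from the algorithm's
  published source; the configuration used here specifies only the
  population size, role split and iteration cap, so other implementations
  of the same algorithm may differ in detail.
* Whether optimization fitness and final evaluation should share CV folds
  was an open choice; they share them here, which slightly favors the
  selected parameters when re-evaluated on the same folds.  The planted
  recovery results are reported with a fresh fold seed in
  `cross_validate_model`, where this bias does not apply.
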