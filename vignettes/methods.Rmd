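---
title: "Small-sample augmentation and surrogate modelling of MD tensile stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-sample augmentation and surrogate modelling of MD tensile stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressaug)
```

## The modelling problem

Coarse-grained molecular-dynamics simulations of natural rubber produce a
handful of expensive observations relating three descriptors — the
phospholipid + protein mass fraction ω, the hydrogen-bond strength εH and
the non-hydrogen-bond strength εNH (both kcal·mol⁻¹) — to the tensile
stress at 600% strain (MPa). With fewer than a hundred runs, flexible
regressors overfit and their apparent skill depends strongly on the chance
train/test split. The package implements a complete small-sample pipeline:
Gaussian neighbourhood augmentation, boundary oversampling of the minority
sampling cluster, a regularised boosted-tree surrogate, a repeated-split
robustness protocol, and exact Shapley interpretation.

## NNI augmentation

Every original sample seeds `points_per_sample` synthetic rows. Feature j of
a synthetic row is drawn from a normal distribution centred on the parent's
value, with variance

σ²ⱼ = (λ / m) · Σᵢ xᵢⱼ,

i.e. λ times the feature mean over the m *original* rows. σ²ⱼ is computed
once and never updated as synthetics accumulate, so augmentation is a single
pass and the count law |output| = m·(k+1) holds exactly (86 originals with
k = 20 give 1806 rows). λ (default 0.1) scales the neighbourhood: λ = 0
duplicates parents, large λ blurs the design. Because the variance is λ
times a *mean*, the parameterisation presumes non-negative feature scales; a
feature with a negative mean raises an error rather than silently taking an
absolute value.

Two choices here were genuinely open:

* **Synthetic targets.** The augmentation literature this follows does not
  say what y a synthetic point receives. The default, `inherit_parent`,
  copies the parent's target — consistent with reading the method as "each
  synthetic lives in its parent's neighbourhood". The alternative,
  `knn_idw`, assigns an inverse-distance-weighted mean of the nearest
  original targets in standardized feature space, the natural reading when
  the method is described as a KD-tree interpolation. Both are implemented;
  neither is asserted as canonical.
* **Clipping.** The Gaussian neighbourhood is unbounded, so synthetic
  features may leave physical ranges. They are not clipped by default
  (clipping would pile mass on the boundary and bias σ²ⱼ);
  `clamp_nonnegative = TRUE` floors features at zero when a column is
  physically non-negative.

## Imbalance detection and boundary SMOTE for regression

Simulation campaigns concentrate where the design is interesting, so the
augmented cloud is clustered. K-means (Lloyd's algorithm on z-scored
features, 300 iterations, best of 10 random restarts) with K = 2 (a plain
config knob) labels the clusters; the smaller one is the minority, ties
going to the lower index.

Minority rows are then classified by the Borderline rule: among each
minority row's `m_neighbors` nearest rows (standardized Euclidean, self
excluded) count the majority members c; rows with c < m/2 are SAFE, c = m
are NOISE, and m/2 ≤ c < m are DANGER — the boundary points that seed
oversampling. `n_synth = ceiling(target_ratio · |majority|) − |minority|`
synthetics are drawn: a danger row x_d (round-robin), one of its
`k_neighbors` nearest minority rows x_nn, and u ~ Uniform(0,1) give
x_new = x_d + u·(x_nn − x_d).

SMOTE is a classification method; for a regression target the package
interpolates y with the *same* u (`interpolate_target = TRUE`), which keeps
synthetics on the local linear response between their parents and makes
every synthetic row verifiable by solving the per-row linear system for u.
Only the minority cluster is oversampled. An empty danger set (perfectly
separated clusters) falls back to classic SMOTE over all minority rows, with
a message.

## The surrogate and its baselines

The surrogate is squared-error gradient boosting with L2 leaf regularization
(n_trees = 55, eta = 0.16, max_depth = 8, reg_lambda = 120 by default), run
single-threaded with no row or column subsampling, min_child_weight 1 and
the base score pinned to the training mean — the minimal deterministic
configuration, so refits with the same seed, spec and data are identical and
a 1-tree, depth-1, unit-rate fit reduces to the best regression stump
(tested against brute force). The heavy leaf regularization is what makes
the model sane at these data sizes: on 86 raw rows the leaves are so small
that predictions shrink strongly toward the mean, and it is the augmentation
that restores enough per-leaf mass for the trees to express the response —
the mechanism behind the pipeline's measured benefit over fitting the raw
rows.

Baselines: ordinary least squares with intercept (closed form; rank-deficient
designs fall back to the minimum-norm solution, with a message) and RBF
ε-insensitive support-vector regression on z-scored features (cost 1,
ε = 0.1, kernel width 1/d on the standardized scale; a target entirely
inside the ε-tube leaves no support vectors and degenerates to the constant
mean).

`cv_score()` averages out-of-fold R² over a random near-equal partition
(default 10 folds). Singleton test folds are rejected — R² is undefined on
one observation — so folds ≤ n/2. `tune_surrogate()` sweeps the four grids
coordinate-wise in the fixed order n_trees → eta → max_depth → reg_lambda,
holding the rest at current values, with the *same* fold seed for every
candidate so the learning curves are comparable; ties break toward the
smaller, more regular value. The reg_lambda grid {0, 1, 10, 60, 120, 240}
brackets the default optimum since no canonical grid exists for it.

## Metrics and the robustness protocol

R² = 1 − SS_res/SS_tot may be negative and requires a non-constant y.
Coverage is

Cov = (1/N) · Σᵢ h( |Xᵢ − X̂ᵢ| / (2·sd(|Xᵢ|)) ),  h(x) = 1 for x ≤ 1,

the fraction of predictions whose absolute error is at most twice the
standard deviation of the absolute observed values, the boundary counting as
covered. The spread is computed on the evaluation set with the N−1
denominator — the only reading that makes the h argument dimensionless and
keeps Cov in [0, 1].

`evaluate_robustness()` repeats a seeded random holdout (default
test_fraction 0.1, mirroring the 10-fold regime; 999 splits by default),
fitting every model recipe per split. Augmentation is *not* re-run per
split, so synthetic neighbours of test rows can sit in training — exactly
the optimism risk the `test_originals_only` mode addresses by drawing test
rows from the original rows only. That leakage-safe mode is what the
package's own benchmark comparisons use. Desk-scale runs in the tests and
the acceptance script use 99 splits (and 20-seed batteries for the
recovery-rate checks); the protocol is identical at 999, only slower.

## Exact Shapley attribution

Attributions are interventional Shapley values computed exactly by
enumerating all 2^d coalitions: v(S) is the mean model prediction over the
background table with the coalition's features replaced by the explained
row's values, and φⱼ sums the weighted marginal contributions. At d = 3
this is 8 coalitions — cheap, dependency-free, and verifiable against the
d!-permutation form (the test suite checks agreement to 1e-10 and local
accuracy base + Σφ = prediction to 1e-8). The background defaults to the
explained table itself (marginal expectation over the empirical
distribution). Global importance ranks features by mean |φ|, ties keeping
column order. The conditional (tree-path-dependent) expectation variant is
out of scope.

`predict_surface()` evaluates the surrogate on an εH×ω grid at fixed εNH
(default 0.38 kcal·mol⁻¹, the background non-bonded strength). The default
grid is 200×200 — the same picture as a multi-million-point sweep at desk
scale — and leaving the training envelope triggers an extrapolation warning.

## The synthetic benchmark

The generator stands in for the unshared MD campaign and fixes the *study
conditions* for every test:

* **Design**: n = 86 points from a two-blob truncated Gaussian mixture
  (weights 0.4/0.6; centers (8, 1.0, 0.3) and (20, 3.4, 0.5) with spreads
  (3, 0.4, 0.15) and (3.5, 0.7, 0.2) in (ω, εH, εNH)), rejection-sampled
  into the box ω ∈ [0, 30], εH ∈ [0.38, 5], εNH ∈ [0, 1]. Rejection, not
  clipping, avoids boundary atoms; 1000 rejections per row is an error. The
  blob separation is chosen so K-means recovers the planted membership
  (ARI ≥ 0.9 in at least 18 of 20 seeds), making the imbalance stage
  testable. ω's numeric range is an assumption, not a reconstruction — no
  range is published for it.
* **Response**: TS = β₀ + β_H·εH + β_ω·ω + β_NH·εNH + β_int·ω·max(εH − τ, 0)
  with defaults β₀ = 2, β_H = 4, β_ω = 0.3, β_NH = 0.1, β_int = 0.4,
  τ = 2.5. This is the minimal form satisfying every qualitative constraint
  the benchmark must plant: all effects positive; mean absolute partial
  effects over the box ordered εH > ω > εNH (checked by numeric
  integration); and a hinge interaction so that at high εH a small change in
  ω moves the stress a lot, while at low εH it barely does.
* **Noise**: Gaussian with sd defaulting to 5% of the surface's range over
  the box (≈ 2.4 MPa), which puts the default pipeline's held-out R² in the
  mid-0.8s to low-0.9s — informative, neither trivial nor hopeless.

What the benchmark does *not* emulate: MD observation noise is unlikely to
be homoscedastic Gaussian; the true response need not be piecewise-linear;
and the published post-SMOTE cluster counts for the real data (both clusters
growing, 757→1007 and 1049→1181) cannot arise from minority-only
oversampling, so they are not reproduced here — total counts after balancing
depend on the seed's cluster split. Coverage also saturates at ~1 on the
benchmark: with signal spread ~10 MPa and errors ~2 MPa, essentially no
prediction misses by twice the spread of |y|; the 0.82–0.92 coverage regime
reported for real MD data reflects noise structure the generator does not
plant. Passing tests therefore demonstrate that the algorithms are
implemented correctly and behave as designed under realistic smooth-response
conditions — not that they will achieve any particular accuracy on real MD
output.

## Numerical choices and degenerate inputs

* One global seed is split into named per-stage substreams
  (multiplicative-congruential hash, always < 2³¹), so identical configs
  reproduce byte-identical artifacts and stages can be re-run in isolation.
* λ = 0 and points_per_sample = 0 are valid degenerate augmentations
  (duplicates / pass-through); constant targets are handled by every model;
  zero-variance features pass through standardization unscaled.
* K-means restarts use base R's random seeding with 10 restarts rather than
  a k-means++ initializer; at these data sizes the restart maximum over
  inertia is stable across seeds.
* Distances for the danger rule, SMOTE neighbours and knn labels are all
  computed in the same z-scored space as the clustering, so "boundary" means
  the same thing in every stage.

```{r example, eval = FALSE}
dat <- generate_dataset(seed = 7)
bal <- dat |> augment_nni(seed = 7) |> balance_smote(seed = 7)
model <- fit_surrogate(bal, seed = 7)
evaluate_robustness(bal, models = list(gbt = surrogate_spec(), mlr = "mlr"),
                    spec = eval_spec(n_splits = 99), seed = 7)
importance_ranking(model, dat)
autoplot(predict_surface(model))
```
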