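---
title: "Linear QSAR modelling with GA descriptor selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear QSAR modelling with GA descriptor selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarkit)
```

## The modelling problem

A QSAR study on a small congeneric inhibitor series starts from an activity
table (compound, IC50 in nM) and a wide numeric descriptor matrix, and
wants a model of potency on the pIC50 scale,
`pIC50 = -log10(IC50 × 1e-9)`. Two properties of this setting drive every
design choice in qsarkit:

* **n is tiny and p is large.** Sixty-odd compounds against hundreds of
  descriptors means overfitting is the default outcome, not an accident.
  Selection must be penalized, validation must be aggressive, and
  single-split metrics must be treated as noisy.
* **Predictions are only meaningful near the training chemistry.** An
  applicability domain (AD) is not an optional extra; screening reports
  carry a domain flag on every row.

## The interpretable core: GA-MLR

The primary model is ordinary least squares on standardized descriptors,

$$y = \beta_0 + \beta_1 x_1 + \dots + \beta_k x_k,$$

with the subset chosen by a binary genetic algorithm maximizing

$$\mathrm{Fitness} = R^2_{adj} - k/n .$$

The `k/n` term is a direct complexity tax on top of the adjustment already
inside $R^2_{adj}$; on a 46-compound training set each extra descriptor
costs about 0.022 fitness, which in practice keeps selections in the
single digits unless a descriptor genuinely pays its way.

GA operator choices the fitness definition does not pin down are set to
conventional values and exposed in `ga_config()`: population 50,
tournament size 2, uniform crossover at rate 0.9, per-bit mutation `1/p`,
elitism 1, a 50-generation budget, and early stopping after 10
generations without improvement of the best fitness ("patience"). Because
the best chromosome is always carried over, the best-fitness trace is
non-decreasing — a property the tests assert. Degenerate chromosomes
(empty mask, singular fit, or `k > n - 2`) receive a `-Inf` sentinel
rather than an error, so the population can simply select them away.
Fitness values are memoized per mask, which makes the late, converged
generations nearly free.

The alternative selectors are deliberately plain: bidirectional stepwise
search under the Gaussian concentrated-likelihood AIC
(`n·ln(RSS/n) + 2(k+1)`; additive constants drop out of comparisons), the
same search under BIC (`ln(n)` penalty) restricted to a candidate pool,
and an iterative VIF screen that removes the worst variance-inflation
offender until all VIFs are at most 10 (the conventional cutoff; the
threshold is a parameter). A worthwhile caveat surfaced by simulation:
with several independent noise candidates, stepwise-AIC retains the null
model far less often than intuition suggests — a spurious column enters
whenever its score beats the penalty of 2, which happens with probability
`1 − P(χ²₁ ≤ 2) ≈ 0.16` *per candidate*. The test suite checks the
analytically derived retention rate rather than an optimistic one.

## Preprocessing

The pipeline order is fixed and deliberate:

1. drop zero-variance columns (unscalable),
2. correlation filter at |r| > 0.95, scanning pairs in column order and
   dropping the later member (the tie rule is arbitrary but documented and
   stable),
3. top-50 variance filter **on the raw scale** — after standardization
   every variance is 1 and the ranking would be vacuous,
4. standardization (mean 0, sample SD 1, n−1 denominator) re-estimated on
   the surviving columns of the *training* rows only,
5. stratified 70/30 split on pIC50.

Stratification bins the continuous response into 5 quantile bins and
allocates training slots per bin by floor-plus-largest-remainder with a
seeded random tie-break, so the total training size is exactly
`round(0.7 n)` and, across seeds, each bin's expected training fraction is
0.7. Training-set means and SDs are serialized to a JSON sidecar and are
the only statistics ever used to project test or screening data
(`apply_scaling()`), preventing the classic leakage of scaling on the
pooled data.

## Validation battery

* **Repeated k-fold CV (10×5).** The *entire* fit specification — feature
  selection included — is re-run inside every fold; a spy-based test
  asserts the recipe never sees held-out rows. Fold-level R² on ~9-point
  folds is intrinsically noisy; the report therefore carries empirical
  2.5%/97.5% quantiles, and a test asserts the spread is wide (IQR > 0.2)
  on study-sized data, because a suspiciously tight CV distribution at
  this n usually signals leakage.
* **Y-randomization (B = 50).** The empirical p-value uses the
  permutation-test +1 convention, `p = (1 + #{R²_perm ≥ R²_obs})/(B+1)`,
  so the best attainable value is 1/51 ≈ 0.02 — reported as such, never
  as 0.
* **Leave-cluster-out (k = 4).** k-means on the standardized descriptors;
  each cluster is held out whole. Clusters with fewer than 3 held-out
  points are flagged `unstable`: an R² about the mean of two observations
  is arithmetic, not evidence. External R² is computed about the held-out
  fold's own mean by default; the training-mean convention is available
  via the `center` argument of `metrics()` since published tables rarely
  say which was used.
* **Split conformal (80/20, α = 0.1).** `q_hat` is the
  `⌈(m+1)(1−α)⌉`-th smallest absolute calibration residual, giving
  constant-width intervals with finite-sample marginal coverage ≥ 0.9
  under exchangeability. With m below 9 that order statistic does not
  exist and the interval is honestly infinite (with a warning) rather
  than silently anti-conservative — this genuinely happens at n ≈ 60
  with a 20% calibration split, and is a limitation of the design, not a
  bug.

## Applicability domain

Two complementary views:

* **Mahalanobis.** `D² = (x−μ)ᵀ Σ⁻¹ (x−μ)` with μ, Σ from the
  standardized training rows of the model's descriptors (an option allows
  full-space assessment). The default threshold is the analytic
  χ²(p, 0.95) quantile — 15.507 at p = 8; a fixed-cutoff mode (e.g. 15.0)
  reproduces screening pipelines that apply a hard round number. The two
  modes change flags only, never predictions, and D² is affinely
  invariant — both tested. A singular covariance falls back to a
  `1e-8·mean(diag)` ridge with a message.
* **Williams.** Leverage on the intercept-augmented training design,
  threshold `h* = 3(p+1)/n` (three times the mean training leverage — an
  identity, also tested), crossed with ±3 standardized residuals. The
  residual scale defaults to the training residual SD with `n−p−1`
  denominator, since published Williams plots rarely define theirs.

## Interpretation

For a linear model the Shapley attribution has an exact closed form under
feature independence, `φ_ij = β_j (x_ij − bg_j)`, which satisfies local
accuracy to machine precision — no sampling, no approximation error.
Permutation importance (mean MSE increase over 20 seeded shuffles) is the
model-agnostic companion used for the tree baselines; for a model using a
single feature exactly, its theoretical value is `2·Var(y)`, which the
tests verify by Monte Carlo.

## Screening

`screen()` chains: training-statistics normalization → prediction →
optional conformal band → Mahalanobis flag → hit call. The hit rule is a
strict `pIC50 > 8.0`; a prediction of exactly 8.0 is not a hit.
Outside-domain compounds keep their predictions but are labelled
extrapolations, and `summarize_hits()` singles out the reliable subset
(hits ∩ inside-domain), which is the list worth synthesizing first.

## The synthetic generator and what passing tests mean

`generate()` emulates the statistical structure the analysis assumes: 62
compounds; 50 descriptors on heterogeneous raw scales (names drawn from
the RDF/MoRSE/CPSA/gravitational families); non-informative descriptors
in blocks with within-block correlation 0.5; five injected near-duplicate
pairs at |r| > 0.95 to exercise the correlation filter; and a sparse
linear signal on 8 descriptors whose coefficient magnitudes and signs are
those of the built-in published equation, with activity centred at pIC50
6.7. The default noise SD (0.95) was set so the in-sample OLS R² on the
true support lands near 0.72, matching the realism target for a series of
this size; with those coefficient magnitudes the simulated pIC50 range is
somewhat wider than a typical experimental 5–9 window, a trade-off we
accept in favour of matching the fit quality and coefficient scale.

Deliberate simplifications: descriptor marginals are Gaussian (a
log-normal toggle provides a skewness stress test), real RDF/CPSA
descriptors are neither Gaussian nor linearly related to activity, and
real activity noise is not homoscedastic. Passing tests on these
generators therefore demonstrate that the *procedures* are correct and
calibrated under their stated assumptions — not that any particular real
dataset satisfies those assumptions.

`generate_query_set()` produces screening candidates with ground-truth
domain labels: in-domain points from the training distribution and
out-of-domain points shifted 8 SD along a random direction of the
standardized space. Note that when the domain is assessed on a
low-dimensional model subspace, a shift living mostly in other
coordinates can legitimately evade the flag — the AD tests therefore
match the assessment space to the shift space.

## Numerical choices, in one place

* OLS via QR (`lm.fit`); rank deficiency is an error naming the dependent
  columns, never a silent drop.
* PLS is NIPALS (PLS1), implemented natively to keep the dependency
  footprint small; at full rank it equals OLS to 1e−6, which is the
  cross-check the tests use.
* Sample SD everywhere uses the n−1 denominator.
* Correlation-filter and variance-filter ties resolve to the earlier
  column; `rank_top_k` ties resolve alphabetically.
* Information criteria use the concentrated Gaussian likelihood; only
  differences are ever compared.
* All randomness flows from explicit integer seeds; the staged pipeline
  derives per-stage seeds as `seed + 1000 × stage index` so stages are
  independently reproducible.

## Known limitations

* Descriptor computation from structures is out of scope; the package
  consumes numeric descriptor tables.
* The built-in published equation ships without its original training
  scaling vector (never published), so it can only be applied to
  descriptors standardized against the caller's own training statistics —
  it is a reference object and a regression oracle, not a turnkey
  predictor for new chemistry.
* Conformal intervals are constant-width (absolute-residual score);
  locally adaptive widths would need a different score.
* Tree-ensemble baselines are comparison adapters; exact tree-SHAP is not
  implemented — attribution is exact only for the linear model.
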