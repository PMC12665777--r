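# qsarkit

Quantitative structure–activity relationship (QSAR) modelling for small
congeneric inhibitor series, built around an interpretable multiple linear
regression whose descriptor subset is chosen by a binary genetic algorithm.
The package is aimed at computational medicinal chemists who need not just a
point prediction of potency but also the audit trail that makes it
decision-grade: resampling validation, a permutation null, distribution-free
prediction intervals, and an explicit applicability domain.

## The model

Activity is modelled on the pIC50 scale, `pIC50 = -log10(IC50 [M])`, as a
linear function of standardized molecular descriptors:

```
y = β₀ + β₁x₁ + β₂x₂ + … + βₖxₖ
```

The descriptor subset is selected by a binary-chromosome genetic algorithm
maximizing the complexity-penalized fitness

```
Fitness = R²adj − k/n
```

where `R²adj = 1 − (1 − R²)(n − 1)/(n − k − 1)`, `k` is the number of
selected descriptors and `n` the number of training compounds. Alternative
selectors (bidirectional stepwise AIC, VIF screening, BIC refit) and
comparison models (NIPALS partial least squares with CV-chosen components,
random-forest and gradient-boosting adapters) are provided.

Around the fitted model the package computes:

- **Validation** — repeated k-fold cross-validation (default 10×5),
  Y-randomization (label-permutation null, default B = 50),
  leave-cluster-out validation (k-means, default 4 clusters), and split
  conformal prediction intervals (default 80/20 calibration, α = 0.1).
- **Applicability domain** — Mahalanobis distance with a χ²(p, 0.95)
  threshold (or a fixed cutoff such as 15.0), and Williams leverage with
  the `h* = 3(p+1)/n` warning threshold and ±3 standardized-residual cuts.
- **Interpretation** — permutation importance (MSE increase) and exact
  additive (Shapley) attribution for linear models.
- **Screening** — queries are normalized with the *training* means/SDs,
  predicted, interval-banded, domain-flagged, and called as hits with a
  strict `pIC50 > 8.0` rule.

A published eight-descriptor KRAS inhibitor GA-MLR equation ships as a
built-in reference model (`published_kras_model()`), and a synthetic-data
generator (`generate()`, `study_shaped_fixture()`) reproduces the
statistical structure of a ~62-compound descriptor table so every stage is
testable without external data.

## Worked example

```r
library(qsarkit)

fx  <- study_shaped_fixture(seed = 7)      # 62 compounds, 58 queries
ds  <- fx$dataset
std <- standardize(ds$X[, ds$true_support])
fit <- fit_ols(std$X, ds$y, scaling = std$scaling)

metrics(ds$y, fit$fitted)
#> n = 62  R2 = 0.7094  RMSE = 0.9192  MAE = 0.7516

y_randomization(ols_fit_spec(), std$X, ds$y, B = 50, seed = 2)$p
#> [1] 0.01960784        # = 1/(B+1): no permuted fit beats the real one

scr <- screen(fit, std$scaling, fx$query$X, std$X, ad_mode = "chi2")
scr
#> Screened 58 compound(s): 17 hit(s) at pIC50 > 8 | 36 inside / 22 outside the domain

head(summarize_hits(scr)$reliable_hits$id)   # hits inside the domain
#> [1] "Q019" "Q025" "Q035" "Q009" "Q017" "Q007"
```

The screening table reports, per candidate, the predicted pIC50, the
conformal interval (when a calibrated model is attached), the Mahalanobis
D², the inside/outside-domain flag, and the hit call; the "reliable hits"
are the hits that fall inside the applicability domain.

A staged command-line style pipeline (`simulate → prepare → select → fit →
validate → ad → screen → report`) is available through `run_pipeline()` /
`run_subcommand()` and the thin wrapper in `inst/scripts/qsarkit.R`, with
YAML configuration and a manifest of artifact digests for reproducibility.

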