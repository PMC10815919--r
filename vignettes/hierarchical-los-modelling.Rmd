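---
title: "Hierarchical Bayesian modelling of cardiac length of stay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian modelling of cardiac length of stay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital length of stay (LoS) after coronary artery bypass grafting (CABG)
is strongly right-skewed: most patients are discharged within ten days, but
a small tail stays for several weeks. Point-prediction models fitted to the
pooled cohort chase the mode of that distribution, reproduce almost none of
its spread, and are useless precisely for the long-stay patients who matter
most for capacity planning. `bayeslos` implements an analysis workflow built
around a hierarchical Bayesian regression that treats the LoS *range* as a
grouping variable, so the model can learn different coefficient regimes for
short, medium, long and very long stays while still sharing information
between them.

## The models

Write $y_i$ for the total LoS of patient $i$ in days (days from admission to
surgery plus days from surgery to discharge) and $x_i \in [0,1]^p$ for the
min–max-scaled pre-operative features. Records are indexed by a level
$\ell_i \in \{0,1,2,3\}$ from half-open LoS bins $[0,10)$, $[10,20)$,
$[20,30)$, $[30,\infty)$; the boundary values 10, 20 and 30 fall in the
upper bin (`assign_level()`).

The hierarchical model (HBM) is

$$y_i \sim \mathrm{TruncNormal}\!\left(\beta_0^{(\ell_i)} + x_i^\top
\beta^{(\ell_i)},\ \sigma;\ 0, \infty\right),$$

with one intercept and one coefficient vector per level, partially pooled
through shared hyperpriors

$$\beta^{(\ell)}_j \sim \mathcal N(\mu_\beta, \sigma_\beta), \quad
\beta_0^{(\ell)} \sim \mathcal N(\mu_{\beta_0}, \sigma_{\beta_0}), \quad
\mu_\cdot \sim \mathcal N(0, 10), \quad \sigma_\cdot \sim
\mathrm{HalfNormal}(10), \quad \sigma \sim \mathrm{HalfNormal}(5).$$

The simple Bayesian model (SBM) is the single-level special case. On the 44
selected features the HBM therefore instantiates $4$ intercepts,
$44 \times 4$ coefficients and one shared noise scale.

Two modelling choices deserve comment:

* **Raw-scale truncated-normal likelihood.** The likelihood operates on the
  LoS in days, truncated below at zero so that predictive draws are always
  non-negative; no upper truncation is imposed. (A log-scale variant of the
  linear predictor is a plausible alternative family; this package commits
  to the raw scale, which is the scale on which all reported statistics
  live.)
* **Hyperprior scales.** The design matrix is scaled to $[0,1]$ but the
  target stays in days, so level intercepts range over roughly 5–35 days.
  Hyperprior scales of 10 days (and a Half-Normal(5) noise prior) are weakly
  informative on that scale; unit-scale hyperpriors would shrink the upper
  level intercepts by many prior standard deviations and visibly bias
  recovery, which we verified in simulation before fixing the defaults.
* **Shared noise scale.** A single $\sigma$ is shared across levels; the
  levels differ in location and coefficients only.

### Posterior computation

The posterior is sampled by a compiled blocked Gibbs sampler
(`sample_posterior()`). The truncation normalizer
$\Phi(\mu_i/\sigma)^{-1}$ is eliminated by data augmentation: each
observation is augmented with its latent *rejected* draws — a
$\mathrm{Geometric}(\Phi(\mu_i/\sigma))$ number of values from the normal
restricted to the negative half-line. Conditional on the augmentation the
likelihood is an ordinary normal product, so

* each level's (intercept, coefficients) block has an exact
  multivariate-normal full conditional, drawn jointly via a Cholesky solve;
* the hyper-means have conjugate normal updates;
* the hyper-scales and $\sigma$ have univariate slice updates
  (stepping-out/shrinkage);
* an ancillarity–sufficiency interweaving move redraws each hyper-scale in
  the non-centered parametrization — where its conditional is an exact
  truncated normal — and rescales the coefficients, which removes the
  funnel-shaped coupling that otherwise slows mixing when the data carry
  little signal and $\sigma_\beta$ is small.

Every conditional is exact, so there are no divergent transitions to count
(`divergence_count` is reported as 0) and no step-size tuning; the warm-up
iterations only serve burn-in. All randomness flows through R's RNG, making
draws bit-reproducible under a seed; chains run sequentially with seeds
derived from the master seed. We validated the sampler three ways: against
the conjugate closed form in the untruncated limit, against a brute-force
grid integration of a small truncated problem, and against an independent
MCMC engine (JAGS) on the same model — all three agree within Monte-Carlo
error. Convergence is monitored with a split-chain Gelman–Rubin statistic
(`rhat()`; constant chains return exactly 1, values above 1.05 are flagged).

### Prediction and the oracle caveat

Test-time prediction needs a level for each record. `predict()` offers two
modes. `"oracle"` derives the level from the *observed* test LoS — this
replicates the reference evaluation protocol and produces the dramatic
error reduction of the hierarchical model, but it leaks the outcome into
the prediction and must be read as "error conditional on knowing the LoS
range", not as an honest forecast. `"marginal"` mixes the level-specific
predictive distributions with training-set level frequencies and is
leakage-free; its accuracy is close to the pooled model, which is exactly
what one should expect when the covariates carry little information about
the level. Both modes are reported deliberately; replication runs default
to oracle.

## The synthetic cohort generator

The registry data behind the reference analysis are not deposited, so the
package ships a generator (`generate_cohort()`) with two modes.

**Realistic mode** reproduces the *marginal* structure of the reference
cohort of 5363 CABG patients and 68 variables: the two LoS components are
right-skewed integer day counts — admission-to-surgery a negative binomial
calibrated to mean 2.26 and sd 1.94, surgery-to-discharge one plus a
negative binomial calibrated to mean 6.04 and sd 2.97, both capped so the
total stays in 1–65 days — giving an overall LoS with mean ≈ 8.3 and sd
≈ 3.55 (the sum of the two independent calibrated components; the reference
sd of 3.7 would require a positive component correlation that is not
reported and is deliberately not invented). Continuous clinical variables
are truncated normals at the published (min, max, mean, sd); BMI is derived
from weight and height; the two blood pressures are drawn conditionally on
hypertension (means 124/117 mmHg systolic) so the reference-based
imputation rules are exercised on data with the structure they assume;
categorical variables are independent draws at the published label
frequencies, with plausible prevalences for the variables whose frequencies
are not printed. Missing cells are injected completely at random at the
audited per-column rates (0.48% systolic BP, 0.41% for five further
columns). What realistic mode does **not** emulate: any covariate–outcome
association and any cross-covariate correlation (a hook exists but defaults
to independence). Tests passing on this cohort therefore validate the
pipeline mechanics and distributional calibration, not clinical predictive
accuracy.

**Model-faithful mode** draws the outcome exactly from the HBM generative
model with known parameters for parameter-recovery studies: features
uniform on $[0,1]$, levels from the stated proportions (defaults 0.80,
0.15, 0.04, 0.01 — a skew-matching choice, since the true level frequencies
are not published), and LoS from the truncated normal with a
rejection-and-redraw step (at most 1000 attempts) that guarantees each
record's LoS lies in its level's bin. Default intercepts sit at the bin
centres (5, 15, 25, 34 days) so rejection is rare. This mode emits the
design matrix and a continuous `LOS` directly — rounding to integer days
would corrupt the recovery target the mode exists for.

## Preprocessing

`preprocess_cohort()` follows the reference recipe exactly, in an order
that keeps every fitted parameter free of test-row influence: BMI imputed
from weight/height; rows that cannot be imputed (or are missing one of the
three audit columns) dropped, refusing if that would exceed the 5%
benchmark; the seeded 80/20 split drawn; blood pressures imputed with
hypertension-conditional means estimated from training rows only; the
target built as the sum of the two components (and identifiers, dates,
weight, height and the components removed — 61 columns on the packaged
cohort); categoricals label-encoded from 0 with alphabetically sorted
labels (deterministic and locale-independent); and min–max scaling fitted
on the training rows and applied everywhere, without clipping. All encoded
model columns are scaled, not only the continuous ones, so coefficient
magnitudes are comparable across mixed types — the reference text is
ambiguous on this point and `scale_fit(columns = "continuous")` provides
the alternative.

## Feature selection

`permutation_importance()` implements permutation feature importance with a
random forest base model: the training set is split again 80/20, the forest
is fitted on the inner 80%, and each feature's validation column is
replaced by $K$ (default 10; the reference count is unstated) random
permutations of its own observed values — the exact empirical marginal,
severing the link to the outcome with no distributional assumptions. The
importance is the mean increase in validation RMSE over the shared,
once-computed baseline; features with strictly positive importance are
kept, ordered by importance with alphabetical tie-breaks. A constant column
scores exactly zero. The 44-variable reference selection ships as a
packaged list (`los_selected_features()`) so replication runs can use the
identical feature set.

## Baselines and evaluation

Eight frequentist regressors run behind a uniform `fit_baseline()` contract
with the reference hyperparameters shipped in YAML: SGD linear regression
(compiled, sklearn-style adaptive schedule; the printed "inverse scaling
factor" is the schedule power, "regularization" the L2 weight), Huber
regression (the printed `k = 4` read as the robustness threshold of the
Huber loss), gradient boosted trees, random forest, lasso, ridge,
polynomial SVR (the printed "regularization 0.3" read as the cost C), and
OLS. Penalty conventions are normalized in the config schema (documented in
`inst/extdata/baselines.yaml`); tree-backend parameters with no equivalent
in the R backend are accepted for config fidelity but documented as inert.

`compute_metrics()` reports mean, sample sd, rounded min/max, CV (sd/mean),
adjusted $R^2 \times 100$, RMSE and MAE; `taylor_stats()` reports the
Taylor-diagram triple (correlation, prediction sd, centered RMS
difference), which satisfies the law-of-cosines identity to numerical
precision by construction of a single shared $(n-1)$ sd convention.
`build_report()` assembles the comparison table with the actual target
first and models in ascending RMSE order.

## Numerical choices and degenerate inputs

* Boundary LoS values (10, 20, 30 days) go to the upper bin.
* A training column constant on the training rows scales to 0 everywhere;
  test values outside the training range scale outside $[0,1]$ unclipped.
* The geometric augmentation is capped at $10^5$ rejections per
  observation; the cap can only bind in regions of negligible posterior
  mass ($\Phi(\mu/\sigma) < 10^{-4}$ with positive observed outcomes).
* `sigma = 0` is allowed in the generator (degenerate deterministic draws)
  but not in the fitted model.
* Levels with zero records draw their coefficients from the hyperprior
  conditional — partial pooling handles empty groups natively.

## Problem sizes used in the packaged checks

The shipped tests and the acceptance script use: the full 5363-patient
cohort for calibration and the hierarchical-vs-pooled comparison (4 chains,
1000 kept draws after 500 warm-up for the 44-feature fits); a 3000-record,
8-feature, $\sigma = 1$ model-faithful cohort with 4 chains × 1500 kept
draws (1000 warm-up) for parameter recovery; and 20 seeded replicates of a
500-record, 6-feature design for the permutation-importance properties.
These sizes give stable Monte-Carlo behaviour for every quantity asserted;
the reference sampling configuration (4 chains × 3000 draws, 1000 tuning
steps) remains the package default for analysis runs.

## Known limitations

* Realistic mode carries no covariate signal, so oracle-mode error
  reductions on it quantify the value of level information alone.
* The generator's unpublished categorical prevalences and the level
  proportions are calibrated judgments, not reference values.
* No model-comparison criteria (WAIC/LOO) and no reproduction of the
  reference per-coefficient estimates, which depend on the inaccessible
  registry.
* A single shared noise scale; heteroscedastic extensions are out of scope.
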