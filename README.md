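# bayeslos

Hierarchical Bayesian length-of-stay (LoS) modelling for cardiac surgery
cohorts.

Hospital stay after coronary artery bypass grafting (CABG) is strongly
right-skewed: most patients leave within ten days, a few stay for weeks.
Models fitted to the pooled cohort predict the mode and reproduce almost
none of the spread, which makes them useless for the long-stay patients who
drive capacity planning. `bayeslos` is for biostatisticians and clinical
data scientists who want to model that skewness instead of trimming it: it
treats the LoS *range* as a grouping level and fits a partially pooled
regression with a truncated-normal likelihood, alongside the standard
pooled alternatives for comparison.

## The model

With `y_i` the LoS in days, `x_i` the min–max-scaled pre-operative
features and level `l_i ∈ {0,1,2,3}` from the half-open bins `[0,10)`,
`[10,20)`, `[20,30)`, `[30,∞)`:

    y_i ~ TruncNormal( beta0[l_i] + x_i' beta[l_i, ] , sigma ; 0, ∞ )

    beta[l, j] ~ Normal(mu_beta,  sigma_beta)      (partial pooling)
    beta0[l]   ~ Normal(mu_beta0, sigma_beta0)
    mu_*  ~ Normal(0, 10),  sigma_* ~ HalfNormal(10),  sigma ~ HalfNormal(5)

The simple Bayesian model (SBM) is the single-level special case. On the
packaged 44-feature selection the hierarchical model (HBM) instantiates 4
intercepts, 176 coefficients and one shared noise scale. The posterior is
drawn by a compiled blocked Gibbs sampler that removes the truncation
normalizer by latent-rejection data augmentation, so every conditional is
exact; see the vignette (`vignettes/hierarchical-los-modelling.Rmd`) for
the algorithm and its validation against closed forms, grid integration
and an independent MCMC engine.

The package also ships a calibrated synthetic CABG cohort generator (the
registry behind the reference analysis is not public), the leakage-free
preprocessing recipe, permutation feature importance, eight frequentist
baselines with the reference hyperparameters, and the full evaluation
suite (RMSE, MAE, dispersion statistics, adjusted R², Taylor statistics).

## Worked example

```r
library(bayeslos)

coh  <- generate_cohort(default_cohort_spec(seed = 5))   # 5363 x 68 cohort
prep <- preprocess_cohort(coh$table, seed = 5)           # impute/split/encode/scale
X <- as.matrix(prep$matrix$values); y <- prep$matrix$target
tr <- prep$split$train; te <- prep$split$test
Xs <- X[, los_selected_features()]                       # 44 reference features

hbm <- sample_posterior(los_model(Xs[tr, ], y[tr], kind = "hbm"),
                        chains = 4, draws = 1000, tune = 500, seed = 3)
sbm <- sample_posterior(los_model(Xs[tr, ], y[tr], kind = "sbm"),
                        chains = 4, draws = 1000, tune = 500, seed = 3)

preds <- list(
  HBM = predict(hbm, Xs[te, ], level_mode = "oracle", y_test = y[te])$.pred,
  SBM = predict(sbm, Xs[te, ], level_mode = "oracle", y_test = y[te])$.pred
)
build_report(preds, y[te], p = ncol(Xs))
```

Output from this exact run:

```
LoS model comparison ( 2 models )
  model mean   sd min max   cv adj_r_squared rmse  mae    r crmsd
 Actual 8.15 3.37   1  22 0.41             -    -    -    -     -
    HBM 8.28 2.87   6  21 0.35         65.31 1.94 1.64 0.82  1.94
    SBM 8.35 0.07   8   9 0.01         -4.62 3.37 2.71 0.03  3.37
```

Reading it: both models match the mean stay (~8.2 days), but only the
hierarchical model reproduces the spread (prediction sd 2.87 vs the actual
3.37; the pooled model collapses to 0.07) and cuts RMSE from 3.37 to 1.94
days. `oracle` mode indexes each test record by its observed LoS range —
the reference evaluation protocol, which leaks the outcome; pass
`level_mode = "marginal"` for the honest leakage-free mixture forecast
(see the vignette's discussion). `tidy()`, `glance()`,
`summarize_coefficients()`, `rhat()` and `autoplot()` expose posterior
summaries, per-level coefficient tables, convergence diagnostics and trace
plots; `run_pipeline(los_config(...))` executes the whole workflow
(simulate → preprocess → select → fit → evaluate) into a run directory.

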