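# Reference hyperparameter configuration for the eight baseline regressors.
# Backend mapping notes:
#   sgd_linear: squared loss + L2 penalty; `regularization` is the penalty
#     weight, `inverse_scaling_factor` the power of the inverse-scaling
#     learning-rate schedule (used when learning_rate = invscaling; the
#     adaptive schedule divides the step by 5 when the epoch loss plateaus).
#   huber: `k` is the robustness threshold of the Huber loss (residual scale
#     beyond which the loss becomes linear).
#   gradient_boosted_trees: min_samples_split / min_samples_leaf /
#     max_features are accepted for config fidelity but inert for the xgboost
#     backend, which enforces min_child_weight instead.
#   random_forest: bootstrap false means every tree sees the full training
#     set (sampling without replacement, fraction 1); min_samples_split is
#     inert for the ranger backend, which enforces min_samples_leaf.
#   lasso/ridge: `lambda` is the penalty weight on the objective
#     (1/2n)*RSS + lambda*|b|_1  and  RSS + lambda*|b|_2^2 respectively.
#   svr_poly: `regularization` is the cost parameter C of epsilon-SVR.
sgd_linear:
  learning_rate: adaptive
  inverse_scaling_factor: 0.899
  regularization: 0.890
  eta0: 0.01
  max_iter: 200
huber:
  k: 4
gradient_boosted_trees:
  subsample: 0.8
  n_estimators: 1800
  min_samples_split: 5
  min_samples_leaf: 4
  min_child_weight: 6
  max_features: auto
  max_depth: 68
  learning_rate: 0.01
  colsample_bytree: 0.2
  booster: gbtree
  alpha: 0.8
  lambda: 0.8
random_forest:
  n_estimators: 1200
  min_samples_split: 10
  min_samples_leaf: 4
  max_features: sqrt
  max_depth: 20
  bootstrap: false
lasso:
  lambda: 0.01
ridge:
  lambda: 1.08
svr_poly:
  kernel: polynomial
  degree: 2
  regularization: 0.3
ols: {}
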