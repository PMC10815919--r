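// Blocked Gibbs sampler for simple and hierarchical Bayesian regression with
// a truncated-at-zero normal likelihood.
//
// The truncation normalizer 1/Phi(mu_i/sigma) is removed by data
// augmentation: each observation is augmented with its latent rejected
// draws -- K_i ~ Geometric(Phi(mu_i/sigma)) values from the normal
// restricted to the negative half-line. Conditional on the augmented data
// the likelihood is an ordinary normal product, so each level's
// (intercept, coefficients) block has an exact multivariate-normal full
// conditional, the hyper-means are conjugate normal updates, and the scale
// parameters have cheap univariate slice updates. Marginalizing the latent
// rejections recovers the truncated-normal model exactly.
//
// All random numbers come from R's RNG so draws are reproducible under
// set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Phi(z) with a shortcut where it is 1 at double precision.
static inline double phi_cdf(double z) {
  if (z > 7.5) return 1.0;
  return R::pnorm(z, 0.0, 1.0, 1, 0);
}

// Univariate slice sampler (Neal 2003, stepping out + shrinkage) on
// (lower, Inf). logf must be finite at x0.
template <typename F>
static double slice_update(double x0, F logf, double w, double lower) {
  double logy = logf(x0) - R::exp_rand();
  double u = R::unif_rand();
  double L = x0 - w * u;
  double Rr = L + w;
  int steps = 50;
  while (L > lower && steps-- > 0 && logf(L) > logy) L -= w;
  if (L < lower) L = lower;
  steps = 50;
  while (steps-- > 0 && logf(Rr) > logy) Rr += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = R::runif(L, Rr);
    if (logf(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else Rr = x1;
  }
  return x0;  // pathological shrinkage; keep current value
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(const arma::mat& X, const arma::vec& y,
                 const arma::ivec& level, int L,
                 List prior, int draws, int tune,
                 arma::mat init_B, double init_sigma,
                 double init_mu_b0, double init_sd_b0,
                 double init_mu_b, double init_sd_b) {
  const int n = X.n_rows;
  const int P = X.n_cols;
  const int Q = P + 1;  // intercept + coefficients
  const int KCAP = 100000;  // guard against runaway augmentation

  const double mu_loc = as<double>(prior["mu_loc"]);
  const double mu_scale = as<double>(prior["mu_scale"]);
  const double sigma_scale = as<double>(prior["sigma_scale"]);
  const double noise_scale = as<double>(prior["noise_scale"]);
  const bool fix_mu = !Rf_isNull(prior["fixed_mu"]);
  const bool fix_sd = !Rf_isNull(prior["fixed_sigma"]);
  const bool fix_noise = !Rf_isNull(prior["fixed_noise"]);
  const double fixed_mu = fix_mu ? as<double>(prior["fixed_mu"]) : 0.0;
  const double fixed_sd = fix_sd ? as<double>(prior["fixed_sigma"]) : 1.0;
  const double fixed_noise = fix_noise ? as<double>(prior["fixed_noise"]) : 1.0;

  // Per-level observed sufficient statistics of the design [1, X].
  std::vector<arma::uvec> idx(L);
  std::vector<arma::mat> A(L);   // Z'Z
  std::vector<arma::vec> v(L);   // Z'y
  std::vector<arma::mat> Z(L);
  std::vector<arma::vec> yl(L);
  for (int l = 0; l < L; ++l) {
    idx[l] = arma::find(level == l);
    arma::mat Zl(idx[l].n_elem, Q);
    if (idx[l].n_elem > 0) {
      Zl.col(0).ones();
      Zl.cols(1, Q - 1) = X.rows(idx[l]);
      yl[l] = y.elem(idx[l]);
    } else {
      yl[l] = arma::vec();
    }
    Z[l] = Zl;
    A[l] = Zl.t() * Zl;
    v[l] = (idx[l].n_elem > 0) ? arma::vec(Zl.t() * yl[l])
                               : arma::zeros<arma::vec>(Q);
  }

  arma::mat B = init_B;  // L x Q, col 0 intercept
  double sigma = fix_noise ? fixed_noise : init_sigma;
  double mu_b0 = fix_mu ? fixed_mu : init_mu_b0;
  double mu_b = fix_mu ? fixed_mu : init_mu_b;
  double sd_b0 = fix_sd ? fixed_sd : init_sd_b0;
  double sd_b = fix_sd ? fixed_sd : init_sd_b;

  // Current linear predictor per level.
  std::vector<arma::vec> mu(L);
  for (int l = 0; l < L; ++l)
    if (idx[l].n_elem > 0) mu[l] = Z[l] * B.row(l).t();

  // Latent-rejection bookkeeping per observation (within level blocks):
  // K = number of rejections, s = sum of rejected values, q = sum of squares.
  std::vector<arma::vec> Kv(L), sv(L), qv(L);
  for (int l = 0; l < L; ++l) {
    Kv[l] = arma::zeros<arma::vec>(idx[l].n_elem);
    sv[l] = arma::zeros<arma::vec>(idx[l].n_elem);
    qv[l] = arma::zeros<arma::vec>(idx[l].n_elem);
  }

  const int n_iter = tune + draws;
  const int npar = L + L * P + 5;  // beta0, beta, sigma, 4 hypers
  arma::mat out(draws, npar);
  long aug_total = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- 1. latent rejections given (B, sigma) ---
    for (int l = 0; l < L; ++l) {
      const arma::uword nl = idx[l].n_elem;
      for (arma::uword i = 0; i < nl; ++i) {
        double m = mu[l][i];
        double p_acc = phi_cdf(m / sigma);
        if (p_acc >= 1.0) { Kv[l][i] = 0; sv[l][i] = 0; qv[l][i] = 0; continue; }
        double p_rej = 1.0 - p_acc;
        int K = (p_acc <= 0.0) ? KCAP : (int)std::min((double)KCAP, R::rgeom(p_acc));
        double s = 0.0, q = 0.0;
        for (int k = 0; k < K; ++k) {
          // draw from Normal(m, sigma) restricted to (-Inf, 0)
          double u = R::runif(0.0, p_rej);
          double t = m + sigma * R::qnorm(u, 0.0, 1.0, 1, 0);
          if (t > 0.0) t = 0.0;  // numerical guard
          s += t;
          q += t * t;
        }
        Kv[l][i] = K; sv[l][i] = s; qv[l][i] = q;
        aug_total += K;
      }
    }

    // --- 2. coefficient blocks: exact MVN conditionals on augmented data ---
    for (int l = 0; l < L; ++l) {
      arma::vec d0(Q), m0(Q);
      d0[0] = 1.0 / (sd_b0 * sd_b0);
      m0[0] = mu_b0;
      for (int j = 1; j < Q; ++j) { d0[j] = 1.0 / (sd_b * sd_b); m0[j] = mu_b; }
      arma::mat Aaug = A[l];
      arma::vec vaug = v[l];
      const arma::uword nl = idx[l].n_elem;
      for (arma::uword i = 0; i < nl; ++i) {
        if (Kv[l][i] == 0) continue;
        arma::vec zi = Z[l].row(i).t();
        Aaug += Kv[l][i] * (zi * zi.t());
        vaug += sv[l][i] * zi;
      }
      arma::mat Qm = Aaug / (sigma * sigma);
      Qm.diag() += d0;
      arma::vec rhs = vaug / (sigma * sigma) + d0 % m0;
      arma::mat U = arma::chol(Qm);                    // Qm = U'U
      arma::vec m = arma::solve(Qm, rhs, arma::solve_opts::likely_sympd);
      arma::vec zdr(Q);
      for (int j = 0; j < Q; ++j) zdr[j] = R::norm_rand();
      arma::vec theta = m + arma::solve(arma::trimatu(U), zdr);
      B.row(l) = theta.t();
      if (nl > 0) mu[l] = Z[l] * theta;
    }

    // --- 3. hyper-means: conjugate normal updates ---
    if (!fix_mu) {
      double prec0 = 1.0 / (mu_scale * mu_scale);
      double prec = prec0 + L / (sd_b0 * sd_b0);
      double mean = (mu_loc * prec0 + arma::accu(B.col(0)) / (sd_b0 * sd_b0)) / prec;
      mu_b0 = mean + R::norm_rand() / std::sqrt(prec);
      double nb = static_cast<double>(L) * P;
      double sum_b = arma::accu(B.cols(1, Q - 1));
      prec = prec0 + nb / (sd_b * sd_b);
      mean = (mu_loc * prec0 + sum_b / (sd_b * sd_b)) / prec;
      mu_b = mean + R::norm_rand() / std::sqrt(prec);
    }

    // --- 4. hyper-scales: slice updates under half-normal priors ---
    if (!fix_sd) {
      double ss0 = arma::accu(arma::square(B.col(0) - mu_b0));
      sd_b0 = slice_update(sd_b0, [&](double s) {
        if (s <= 1e-10) return -1e300;
        return -L * std::log(s) - ss0 / (2.0 * s * s)
               - s * s / (2.0 * sigma_scale * sigma_scale);
      }, 1.0, 1e-10);
      double ssb = arma::accu(arma::square(B.cols(1, Q - 1) - mu_b));
      double nb = static_cast<double>(L) * P;
      sd_b = slice_update(sd_b, [&](double s) {
        if (s <= 1e-10) return -1e300;
        return -nb * std::log(s) - ssb / (2.0 * s * s)
               - s * s / (2.0 * sigma_scale * sigma_scale);
      }, 1.0, 1e-10);
    }

    // --- 4b. ancillarity-sufficiency interweaving for the hyper-scales ---
    // In the non-centered parametrization (coefficients = mu + s * tilde)
    // the conditional of the scale s given the standardized coefficients and
    // the augmented data is an exact truncated normal, because the exponent
    // is quadratic in s. Redrawing s there and rescaling breaks the funnel
    // coupling that slows the centered updates when s is small.
    if (!fix_sd && sd_b > 1e-8) {
      arma::mat Bt = (B.cols(1, Q - 1) - mu_b) / sd_b;  // standardized coefs
      double Aq = 0.0, Bq = 0.0;
      for (int l = 0; l < L; ++l) {
        const arma::uword nl = idx[l].n_elem;
        if (nl == 0) continue;
        arma::vec ci = Z[l].cols(1, Q - 1) * Bt.row(l).t();
        arma::vec ai = B(l, 0) + mu_b * arma::sum(Z[l].cols(1, Q - 1), 1);
        for (arma::uword i = 0; i < nl; ++i) {
          double w = 1.0 + Kv[l][i];
          Aq += w * ci[i] * ci[i];
          Bq += ci[i] * ((yl[l][i] - ai[i]) + sv[l][i] - Kv[l][i] * ai[i]);
        }
      }
      double prec = Aq / (sigma * sigma) + 1.0 / (sigma_scale * sigma_scale);
      double mean = (Bq / (sigma * sigma)) / prec;
      double sdv = 1.0 / std::sqrt(prec);
      double plo = R::pnorm(0.0, mean, sdv, 1, 0);
      if (plo < 1.0 - 1e-12) {
        double s_new = R::qnorm(R::runif(plo, 1.0), mean, sdv, 1, 0);
        if (s_new > 1e-10 && std::isfinite(s_new)) {
          sd_b = s_new;
          B.cols(1, Q - 1) = mu_b + s_new * Bt;
          for (int l = 0; l < L; ++l)
            if (idx[l].n_elem > 0) mu[l] = Z[l] * B.row(l).t();
        }
      }
    }
    if (!fix_sd && sd_b0 > 1e-8) {
      arma::vec b0t = (B.col(0) - mu_b0) / sd_b0;
      double Aq = 0.0, Bq = 0.0;
      for (int l = 0; l < L; ++l) {
        const arma::uword nl = idx[l].n_elem;
        if (nl == 0) continue;
        arma::vec ai = mu_b0 + Z[l].cols(1, Q - 1) * B.row(l).subvec(1, Q - 1).t();
        double c = b0t[l];
        for (arma::uword i = 0; i < nl; ++i) {
          double w = 1.0 + Kv[l][i];
          Aq += w * c * c;
          Bq += c * ((yl[l][i] - ai[i]) + sv[l][i] - Kv[l][i] * ai[i]);
        }
      }
      double prec = Aq / (sigma * sigma) + 1.0 / (sigma_scale * sigma_scale);
      double mean = (Bq / (sigma * sigma)) / prec;
      double sdv = 1.0 / std::sqrt(prec);
      double plo = R::pnorm(0.0, mean, sdv, 1, 0);
      if (plo < 1.0 - 1e-12) {
        double s_new = R::qnorm(R::runif(plo, 1.0), mean, sdv, 1, 0);
        if (s_new > 1e-10 && std::isfinite(s_new)) {
          sd_b0 = s_new;
          B.col(0) = mu_b0 + s_new * b0t;
          for (int l = 0; l < L; ++l)
            if (idx[l].n_elem > 0) mu[l] = Z[l] * B.row(l).t();
        }
      }
    }

    // --- 5. noise scale: slice on the augmented normal likelihood ---
    if (!fix_noise) {
      // SSR over observed and latent values at the *current* linear
      // predictor: sum (y - mu)^2 + sum (z - mu)^2 expanded through the
      // per-observation sums.
      double ssr = 0.0, m_total = 0.0;
      for (int l = 0; l < L; ++l) {
        const arma::uword nl = idx[l].n_elem;
        if (nl == 0) continue;
        ssr += arma::accu(arma::square(yl[l] - mu[l]));
        for (arma::uword i = 0; i < nl; ++i) {
          if (Kv[l][i] == 0) continue;
          double m = mu[l][i];
          ssr += qv[l][i] - 2.0 * m * sv[l][i] + Kv[l][i] * m * m;
          m_total += Kv[l][i];
        }
      }
      double ntot = n + m_total;
      sigma = slice_update(sigma, [&](double s) {
        if (s <= 1e-10) return -1e300;
        return -ntot * std::log(s) - ssr / (2.0 * s * s)
               - s * s / (2.0 * noise_scale * noise_scale);
      }, std::max(0.1, sigma / 2.0), 1e-10);
    }

    if (it >= tune) {
      int r = it - tune;
      int c = 0;
      for (int l = 0; l < L; ++l) out(r, c++) = B(l, 0);
      for (int l = 0; l < L; ++l)
        for (int j = 1; j < Q; ++j) out(r, c++) = B(l, j);
      out(r, c++) = sigma;
      out(r, c++) = mu_b0;
      out(r, c++) = sd_b0;
      out(r, c++) = mu_b;
      out(r, c++) = sd_b;
    }
  }

  return List::create(
    _["draws"] = out,
    _["augmented"] = (double)aug_total / (double)n_iter
  );
}

// Stochastic gradient descent for L2-penalized linear least squares,
// sklearn-style schedules: "adaptive" keeps the step until the epoch loss
// stops improving, then divides it by 5; "invscaling" uses eta0 / t^power_t.
// [[Rcpp::export(name = ".sgd_fit")]]
NumericVector sgd_fit(const arma::mat& X, const arma::vec& y,
                      double alpha, double eta0, double power_t,
                      std::string schedule, int max_iter, double tol) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  arma::vec w(p, arma::fill::zeros);
  double b = 0.0;
  double eta = eta0;
  double best_loss = R_PosInf;
  int no_improve = 0;
  long t = 0;

  for (int epoch = 0; epoch < max_iter; ++epoch) {
    // Seeded Fisher-Yates shuffle through R's RNG.
    arma::uvec ord = arma::regspace<arma::uvec>(0, n - 1);
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(R::unif_rand() * (i + 1));
      std::swap(ord[i], ord[j]);
    }
    for (int k = 0; k < n; ++k) {
      ++t;
      if (schedule == "invscaling") eta = eta0 / std::pow((double)t, power_t);
      const arma::uword i = ord[k];
      double err = arma::dot(X.row(i), w) + b - y[i];
      w = w - eta * (err * X.row(i).t() + alpha * w);
      b -= eta * err;
    }
    double loss = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = arma::dot(X.row(i), w) + b - y[i];
      loss += e * e;
    }
    loss = loss / (2.0 * n) + 0.5 * alpha * arma::dot(w, w);
    if (loss < best_loss - tol) { best_loss = loss; no_improve = 0; }
    else if (++no_improve >= 5) {
      if (schedule == "adaptive") { eta /= 5.0; no_improve = 0; if (eta < 1e-6) break; }
      else break;
    }
  }
  NumericVector out(p + 1);
  out[0] = b;
  for (int j = 0; j < p; ++j) out[j + 1] = w[j];
  return out;
}
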