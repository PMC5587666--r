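// Blocked Gibbs sampler for latent Dirichlet process regression.
//
// Model: y = W alpha + X beta + e, e ~ N(0, sigma2e I);
// beta_i | gamma_i = k ~ N(0, sigma2k[k]); gamma_i ~ Cat(pi);
// pi from truncated stick-breaking with nu_k ~ Beta(1, lambda), nu_K = 1;
// sigma2k ~ InvGamma(a_sigma, b_sigma); lambda ~ Gamma(a_lambda, b_lambda);
// sigma2e ~ InvGamma(a_e, b_e); flat prior on alpha.
//
// Single-site beta updates with an in-place residual cache give O(np) sweeps.
// Uses R's RNG throughout so set.seed() on the R side governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // inverse-gamma via reciprocal gamma; R::rgamma takes (shape, scale)
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

static arma::vec stick_weights(const arma::vec& nu) {
  int K = nu.n_elem;
  arma::vec pi(K);
  double rem = 1.0;
  for (int k = 0; k < K; ++k) {
    pi[k] = nu[k] * rem;
    rem *= (1.0 - nu[k]);
  }
  return pi;
}

// [[Rcpp::export(name = ".dpr_gibbs_cpp")]]
List dpr_gibbs_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& W,
                   int K,
                   double a_sigma, double b_sigma,
                   double a_lambda, double b_lambda,
                   double a_e, double b_e,
                   int n_iter, int burn_in, int thin,
                   bool fix_sigma2k, arma::vec sigma2k_init,
                   bool fix_sigma2e, double sigma2e_init,
                   bool fix_pi, arma::vec pi_init,
                   bool fix_alpha, arma::vec alpha_init,
                   bool keep_gamma, bool keep_beta, bool debug) {
  const int n = y.n_elem, p = X.n_cols, c = W.n_cols;
  const int kept_total = (n_iter - burn_in) / thin;

  // precomputations
  arma::vec xtx(p);
  for (int i = 0; i < p; ++i) xtx[i] = arma::dot(X.col(i), X.col(i));
  arma::mat WtW = W.t() * W;
  arma::mat WtWinv;
  if (!fix_alpha) {
    if (!arma::inv_sympd(WtWinv, WtW))
      stop("collinear covariates: W'W is singular");
  }
  arma::mat WtWinv_chol;
  if (!fix_alpha) WtWinv_chol = arma::chol(WtWinv, "lower");

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::ivec gam(p);
  for (int i = 0; i < p; ++i) gam[i] = (int)(unif_rand() * K);
  arma::vec sigma2k = sigma2k_init;
  if (!fix_sigma2k) {
    double vy = arma::var(y);
    for (int k = 0; k < K; ++k)
      sigma2k[k] = std::max(vy * (k + 1.0) / (K * std::max(p, 1)), 1e-6);
  }
  double sigma2e = fix_sigma2e ? sigma2e_init : arma::var(y);
  if (!(sigma2e > 0)) sigma2e = 1.0;
  double lambda = 1.0;
  arma::vec nu(K, arma::fill::value(0.5));
  nu[K - 1] = 1.0;
  arma::vec pi_k = fix_pi ? pi_init : stick_weights(nu);
  arma::vec alpha(c, arma::fill::zeros);
  if (fix_alpha) {
    alpha = alpha_init;
  } else {
    alpha = WtWinv * (W.t() * y);
  }
  arma::vec r = y - W * alpha;  // residual cache: y - W alpha - X beta

  // accumulators and traces
  arma::vec beta_sum(p, arma::fill::zeros);
  arma::vec alpha_sum(c, arma::fill::zeros);
  arma::vec pip_count(p, arma::fill::zeros);
  arma::vec sigma2e_draws(kept_total), lambda_draws(kept_total),
            pve_draws(kept_total), logpost_draws(kept_total);
  arma::mat pi_draws(kept_total, K), sigma2k_draws(kept_total, K);
  arma::imat gamma_counts(kept_total, K);
  arma::imat gamma_draws;
  arma::mat beta_draws;
  if (keep_gamma) gamma_draws.set_size(kept_total, p);
  if (keep_beta) beta_draws.set_size(kept_total, p);

  arma::vec logw(K);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // --- per-SNP assignment and effect updates ---
    for (int i = 0; i < p; ++i) {
      if (beta[i] != 0.0) r += X.col(i) * beta[i];  // add SNP i back
      double xtr = arma::dot(X.col(i), r);
      // gamma_i | beta_i: P(k) prop. to pi_k * N(beta_i; 0, sigma2k[k])
      double b2 = beta[i] * beta[i];
      for (int k = 0; k < K; ++k)
        logw[k] = std::log(pi_k[k]) - 0.5 * std::log(sigma2k[k]) -
                  b2 / (2.0 * sigma2k[k]);
      double mx = logw.max();
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { logw[k] = std::exp(logw[k] - mx); tot += logw[k]; }
      double u = unif_rand() * tot, acc = 0.0;
      int g = K - 1;
      for (int k = 0; k < K; ++k) { acc += logw[k]; if (u <= acc) { g = k; break; } }
      gam[i] = g;
      // beta_i | gamma_i, rest
      double s2 = 1.0 / (xtx[i] / sigma2e + 1.0 / sigma2k[g]);
      double m = s2 * xtr / sigma2e;
      beta[i] = m + std::sqrt(s2) * norm_rand();
      r -= X.col(i) * beta[i];
    }

    // occupancy counts and sums of squares
    arma::ivec nk(K, arma::fill::zeros);
    arma::vec ssk(K, arma::fill::zeros);
    for (int i = 0; i < p; ++i) { nk[gam[i]]++; ssk[gam[i]] += beta[i] * beta[i]; }

    // --- component variances ---
    if (!fix_sigma2k)
      for (int k = 0; k < K; ++k)
        sigma2k[k] = rinvgamma(a_sigma + nk[k] / 2.0, b_sigma + ssk[k] / 2.0);

    // --- sticks, weights, concentration ---
    if (!fix_pi) {
      double sum_log1m = 0.0;
      int above = p;
      for (int k = 0; k < K - 1; ++k) {
        above -= nk[k];  // counts in components > k
        nu[k] = R::rbeta(1.0 + nk[k], lambda + above);
        if (nu[k] >= 1.0) nu[k] = 1.0 - 1e-12;
        if (nu[k] <= 0.0) nu[k] = 1e-12;
        double lg = std::log1p(-nu[k]);
        sum_log1m += std::max(lg, -700.0);
      }
      nu[K - 1] = 1.0;
      pi_k = stick_weights(nu);
      lambda = R::rgamma(a_lambda + K - 1.0, 1.0 / (b_lambda - sum_log1m));
      if (!(lambda > 0)) lambda = 1e-8;
    }

    // --- residual variance ---
    double rss = arma::dot(r, r);
    if (!fix_sigma2e) sigma2e = rinvgamma(a_e + n / 2.0, b_e + rss / 2.0);

    // --- covariate coefficients ---
    if (!fix_alpha) {
      arma::vec yXb = r + W * alpha;  // y - X beta
      arma::vec mu = WtWinv * (W.t() * yXb);
      arma::vec z(c);
      for (int j = 0; j < c; ++j) z[j] = norm_rand();
      arma::vec alpha_new = mu + std::sqrt(sigma2e) * (WtWinv_chol * z);
      r = yXb - W * alpha_new;
      alpha = alpha_new;
      rss = arma::dot(r, r);
    }

    if (debug) {
      arma::vec rchk = y - W * alpha - X * beta;
      if (arma::abs(rchk - r).max() > 1e-8)
        stop("internal consistency error: stale residual cache at sweep %d", it);
    }

    if (!beta.is_finite() || !std::isfinite(sigma2e) || !pi_k.is_finite())
      stop("numerical divergence at sweep %d", it);

    // --- record ---
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < kept_total) {
      arma::vec g_val = y - W * alpha - r;  // X beta
      double vg = arma::var(g_val);
      double pve = vg / (vg + sigma2e);

      // unnormalized log posterior
      double lp = -0.5 * n * std::log(2.0 * M_PI * sigma2e) -
                  rss / (2.0 * sigma2e);
      for (int i = 0; i < p; ++i) {
        int k = gam[i];
        lp += std::log(pi_k[k]) - 0.5 * std::log(2.0 * M_PI * sigma2k[k]) -
              beta[i] * beta[i] / (2.0 * sigma2k[k]);
      }
      if (!fix_sigma2k)
        for (int k = 0; k < K; ++k)
          lp += a_sigma * std::log(b_sigma) - lgamma(a_sigma) -
                (a_sigma + 1.0) * std::log(sigma2k[k]) - b_sigma / sigma2k[k];
      if (!fix_pi) {
        for (int k = 0; k < K - 1; ++k)
          lp += std::log(lambda) + (lambda - 1.0) * std::log1p(-nu[k]);
        lp += a_lambda * std::log(b_lambda) - lgamma(a_lambda) +
              (a_lambda - 1.0) * std::log(lambda) - b_lambda * lambda;
      }
      if (!fix_sigma2e)
        lp += a_e * std::log(b_e) - lgamma(a_e) -
              (a_e + 1.0) * std::log(sigma2e) - b_e / sigma2e;

      int kmin = (int)sigma2k.index_min();
      for (int i = 0; i < p; ++i) if (gam[i] != kmin) pip_count[i] += 1.0;

      beta_sum += beta;
      alpha_sum += alpha;
      sigma2e_draws[kept] = sigma2e;
      lambda_draws[kept] = lambda;
      pve_draws[kept] = pve;
      logpost_draws[kept] = lp;
      pi_draws.row(kept) = pi_k.t();
      sigma2k_draws.row(kept) = sigma2k.t();
      for (int k = 0; k < K; ++k) gamma_counts(kept, k) = nk[k];
      if (keep_gamma)
        for (int i = 0; i < p; ++i) gamma_draws(kept, i) = gam[i] + 1;
      if (keep_beta) beta_draws.row(kept) = beta.t();
      ++kept;
    }
  }

  List out = List::create(
    _["beta_mean"] = beta_sum / kept_total,
    _["alpha_mean"] = alpha_sum / kept_total,
    _["pip"] = pip_count / kept_total,
    _["sigma2e_draws"] = sigma2e_draws,
    _["lambda_draws"] = lambda_draws,
    _["pve_draws"] = pve_draws,
    _["log_posterior_trace"] = logpost_draws,
    _["pi_draws"] = pi_draws,
    _["sigma2k_draws"] = sigma2k_draws,
    _["gamma_counts"] = gamma_counts,
    _["n_kept"] = kept_total);
  if (keep_gamma) out["gamma_draws"] = gamma_draws;
  if (keep_beta) out["beta_draws"] = beta_draws;
  return out;
}
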