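#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for weighted BayesB / BayesC marker models.
//
//   y_i = mu + sum_j Z_ij u_j delta_j + e_i,   e_i ~ N(0, sigma2_e / w_i)
//
// delta_j ~ Bernoulli(1 - pi) a priori (pi held fixed).  BayesC: one common
// effect variance sigma2_u ~ nu_u * S2u / chisq(nu_u).  BayesB: locus-specific
// sigma2_j with the same prior; when a locus is currently excluded its
// proposal variance is a fresh draw from the prior (standard locus sampler).
// delta_j is drawn from the marginal likelihood with u_j integrated out given
// its variance.  Residual variance sigma2_e ~ nu_e * S2e / chisq(nu_e).
// Uses R's RNG: seed from R with set.seed().
//
// [[Rcpp::export]]
List cpp_bayes_mcmc(NumericMatrix Z, NumericVector y, NumericVector w,
                    bool bayesB, double pi, int n_iter, int burnin, int thin,
                    double nu_u, double nu_e, double S2u, double S2e,
                    bool store_samples) {
  int n = Z.nrow(), k = Z.ncol();
  if (y.size() != n || w.size() != n) stop("dimension mismatch");
  if (burnin >= n_iter) stop("burn-in must be shorter than the chain");

  // precompute weighted column cross-products
  std::vector<double> zz(k);
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * Z(i, j) * Z(i, j);
    zz[j] = s;
  }
  double wsum = 0.0;
  for (int i = 0; i < n; ++i) wsum += w[i];

  std::vector<double> u(k, 0.0), sigma2_j(k, S2u);
  std::vector<char> delta(k, 0);
  double mu = 0.0, sigma2_e = S2e > 0 ? S2e : 1.0, sigma2_u = S2u;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i];

  int n_saved = 0;
  for (int it = burnin; it < n_iter; ++it) if ((it - burnin) % thin == 0) ++n_saved;

  NumericVector post_u(k), freq(k);
  NumericVector genvar_s(n_saved), sigma2e_s(n_saved), mu_s(n_saved),
      sigma2u_s(n_saved), ninc_s(n_saved);
  NumericMatrix usamp = store_samples ? NumericMatrix(k, n_saved)
                                      : NumericMatrix(0, 0);

  double log_prior_odds = std::log(1.0 - pi) - std::log(pi > 0 ? pi : 1e-300);
  RNGScope scope;
  int isave = 0;

  for (int it = 0; it < n_iter; ++it) {
    // intercept (weighted)
    double se = 0.0;
    for (int i = 0; i < n; ++i) se += w[i] * (e[i] + mu);
    double mu_new = R::rnorm(se / wsum, std::sqrt(sigma2_e / wsum));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // loci
    for (int j = 0; j < k; ++j) {
      double uj = u[j];
      double rhs = 0.0;
      if (uj != 0.0) {
        for (int i = 0; i < n; ++i) {
          e[i] += Z(i, j) * uj;            // restore residual without locus j
          rhs += w[i] * Z(i, j) * e[i];
        }
      } else {
        for (int i = 0; i < n; ++i) rhs += w[i] * Z(i, j) * e[i];
      }

      double s2;
      if (bayesB) {
        if (!delta[j])                      // proposal variance from prior
          sigma2_j[j] = nu_u * S2u / R::rchisq(nu_u);
        s2 = sigma2_j[j];
      } else s2 = sigma2_u;

      double incl_prob;
      if (pi <= 0.0) incl_prob = 1.0;
      else if (pi >= 1.0) incl_prob = 0.0;
      else {
        double lambda = sigma2_e / s2;
        double logLR = 0.5 * (std::log(lambda) - std::log(zz[j] + lambda)
                              + rhs * rhs / (sigma2_e * (zz[j] + lambda)));
        double lo = log_prior_odds + logLR;
        incl_prob = 1.0 / (1.0 + std::exp(-lo));
      }

      if (R::unif_rand() < incl_prob) {
        double lambda = sigma2_e / s2;
        double denom = zz[j] + lambda;
        double unew = R::rnorm(rhs / denom, std::sqrt(sigma2_e / denom));
        for (int i = 0; i < n; ++i) e[i] -= Z(i, j) * unew;
        u[j] = unew; delta[j] = 1;
        if (bayesB)
          sigma2_j[j] = (nu_u * S2u + unew * unew) / R::rchisq(nu_u + 1.0);
      } else {
        u[j] = 0.0; delta[j] = 0;
      }
    }

    // common effect variance (BayesC)
    if (!bayesB) {
      double ssq = 0.0; int m = 0;
      for (int j = 0; j < k; ++j) if (delta[j]) { ssq += u[j] * u[j]; ++m; }
      sigma2_u = (nu_u * S2u + ssq) / R::rchisq(nu_u + m);
    }

    // residual variance (weighted)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
    sigma2_e = (nu_e * S2e + sse) / R::rchisq(nu_e + n);

    if (it >= burnin && (it - burnin) % thin == 0) {
      int m = 0;
      double gbar = 0.0, gss = 0.0;
      for (int i = 0; i < n; ++i) {
        double gi = y[i] - mu - e[i];
        gbar += gi; gss += gi * gi;
      }
      gbar /= n;
      genvar_s[isave] = (gss - n * gbar * gbar) / (n - 1.0);
      for (int j = 0; j < k; ++j) {
        post_u[j] += u[j];
        if (delta[j]) { freq[j] += 1.0; ++m; }
        if (store_samples) usamp(j, isave) = u[j];
      }
      sigma2e_s[isave] = sigma2_e;
      mu_s[isave] = mu;
      sigma2u_s[isave] = bayesB ? NA_REAL : sigma2_u;
      ninc_s[isave] = m;
      ++isave;
    }
  }

  for (int j = 0; j < k; ++j) { post_u[j] /= n_saved; freq[j] /= n_saved; }

  return List::create(
      _["post_mean_effect"] = post_u, _["model_freq"] = freq,
      _["genvar_samples"] = genvar_s, _["sigma2e_samples"] = sigma2e_s,
      _["mu_samples"] = mu_s, _["sigma2u_samples"] = sigma2u_s,
      _["n_included_samples"] = ninc_s, _["n_saved"] = n_saved,
      _["effect_samples"] = usamp);
}
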