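#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// BayesC Gibbs sampler. Model:
//   y_i = mu + sum_j X_ij a_j delta_j + e_i,   e_i ~ N(0, sigma2_e / w_i)
// Priors: delta_j ~ Bernoulli(1 - pi); a_j | sigma2_a ~ N(0, sigma2_a) with a
// common SNP-effect variance sigma2_a ~ scaled-inv-chi2(nu_a, s2_a); residual
// variance sigma2_e ~ scaled-inv-chi2(nu_e, s2_e). Per-record weights w_i
// scale the residual variance (GenSel-style weighting). Posterior means are
// accumulated after burn_in iterations. Uses R's RNG, so results are
// reproducible from set.seed().
// [[Rcpp::export]]
List bayesc_gibbs_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                      double pi, double nu_a, double s2_a,
                      double nu_e, double s2_e,
                      double sigma2_a_init, double sigma2_e_init,
                      int n_iter, int burn_in, bool fit_intercept,
                      bool update_sigma_a, bool update_sigma_e) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> a((size_t) p, 0.0);
  std::vector<int> del((size_t) p, 0);

  // Weighted diagonal cross-products x_j' W x_j.
  std::vector<double> xwx((size_t) p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    const double* xj = &X(0, j);
    for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
    xwx[j] = s;
  }
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];

  double mu = 0.0;
  if (fit_intercept) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += w[i] * y[i];
    mu = s / sw;
  }
  std::vector<double> e((size_t) n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  double s2a = sigma2_a_init, s2e = sigma2_e_init;
  const double logpi = (pi > 0.0) ? std::log(pi) : 0.0;
  const double log1mpi = (pi < 1.0) ? std::log(1.0 - pi) : 0.0;

  std::vector<double> a_mean((size_t) p, 0.0), inc((size_t) p, 0.0);
  double mu_mean = 0.0, s2a_mean = 0.0, s2e_mean = 0.0;
  int nkeep = 0;

  for (int it = 0; it < n_iter; ++it) {
    int m_in = 0;
    double ssa = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xwx[j] <= 0.0) { a[j] = 0.0; del[j] = 0; continue; }
      const double* xj = &X(0, j);
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += w[i] * xj[i] * e[i];
      r += xwx[j] * a[j];  // restore the effect currently in the residual
      double p1;
      if (pi >= 1.0) {
        p1 = 0.0;
      } else if (pi <= 0.0) {
        p1 = 1.0;
      } else {
        const double v1 = xwx[j] * xwx[j] * s2a + xwx[j] * s2e;
        const double v0 = xwx[j] * s2e;
        const double logd1 = log1mpi - 0.5 * (std::log(v1) + r * r / v1);
        const double logd0 = logpi - 0.5 * (std::log(v0) + r * r / v0);
        p1 = 1.0 / (1.0 + std::exp(logd0 - logd1));
      }
      const double aold = a[j];
      if (p1 > 0.0 && unif_rand() < p1) {
        const double C = xwx[j] + s2e / s2a;
        const double anew = r / C + norm_rand() * std::sqrt(s2e / C);
        a[j] = anew;
        del[j] = 1;
        ++m_in;
        ssa += anew * anew;
        const double diff = anew - aold;
        if (diff != 0.0) for (int i = 0; i < n; ++i) e[i] -= xj[i] * diff;
      } else {
        a[j] = 0.0;
        del[j] = 0;
        if (aold != 0.0) for (int i = 0; i < n; ++i) e[i] += xj[i] * aold;
      }
    }
    if (fit_intercept) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += w[i] * (e[i] + mu);
      const double mun = s / sw + norm_rand() * std::sqrt(s2e / sw);
      const double dmu = mun - mu;
      for (int i = 0; i < n; ++i) e[i] -= dmu;
      mu = mun;
    }
    if (update_sigma_a) {
      s2a = (ssa + nu_a * s2_a) / R::rchisq(nu_a + (double) m_in);
    }
    if (update_sigma_e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += w[i] * e[i] * e[i];
      s2e = (sse + nu_e * s2_e) / R::rchisq(nu_e + (double) n);
    }
    if (!std::isfinite(s2e) || !std::isfinite(s2a))
      stop("BayesC chain diverged (non-finite variance) at iteration %d", it + 1);
    if (it >= burn_in) {
      ++nkeep;
      for (int j = 0; j < p; ++j) {
        a_mean[j] += a[j];
        inc[j] += del[j];
      }
      mu_mean += mu;
      s2a_mean += s2a;
      s2e_mean += s2e;
    }
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }

  if (nkeep < 1) stop("no post-burn-in samples (n_iter <= burn_in)");
  NumericVector eff(p), pin(p);
  for (int j = 0; j < p; ++j) {
    eff[j] = a_mean[j] / nkeep;
    pin[j] = inc[j] / nkeep;
  }
  return List::create(
    _["snp_effects"] = eff,
    _["inclusion_prob"] = pin,
    _["mu"] = mu_mean / nkeep,
    _["sigma2_snp"] = s2a_mean / nkeep,
    _["sigma2_e"] = s2e_mean / nkeep,
    _["n_kept"] = nkeep);
}
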