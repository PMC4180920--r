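// Single-site Gibbs samplers for the two-component marker-effect mixtures.
//
// mode 0 (BayesC): with prior probability pi a SNP effect is exactly zero in
// the current iteration; otherwise it is normal with the common variance
// sigma_w2.
// mode 1 (BSSVS): every SNP always has an effect; with prior probability pi
// it comes from the small-variance component sigma_w2 / c, otherwise from the
// large component sigma_w2.
//
// Residual and common SNP variances have scaled-inverse-chi-square full
// conditionals; the overall mean is an unpenalized location. Uses R's RNG so
// set.seed() in R makes chains bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".gibbs_mixture_cpp")]]
List gibbs_mixture_cpp(const NumericMatrix& Z, const NumericVector& y,
                       int n_iter, int burn_in, int thin, double pi_prior,
                       double c_ratio, int mode, double nu_w, double s2_w,
                       double nu_e, double s2_e) {
  const int n = Z.nrow(), p = Z.ncol();
  if (y.size() != n) stop("dimension mismatch between Z and y");
  if (burn_in >= n_iter) stop("burn-in must be smaller than the chain length");
  if (thin < 1) stop("thinning stride must be at least 1");
  if (pi_prior < 0.0 || pi_prior >= 1.0) stop("pi must lie in [0, 1)");
  if (mode == 1 && c_ratio <= 1.0) stop("variance ratio c must exceed 1");

  // column sums of squares
  std::vector<double> dj(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Z(i, j) * Z(i, j);
    dj[j] = s;
  }

  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep < 1) stop("no kept iterations");
  NumericMatrix keep_w(n_keep, p);
  IntegerMatrix keep_delta(n_keep, p);
  NumericVector keep_mu(n_keep), keep_s2e(n_keep), keep_s2w(n_keep);

  std::vector<double> w(p, 0.0);
  std::vector<int> delta(p, 0);
  double mu = mean(y);
  double s2e = s2_e, s2w = s2_w;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const double log_prior_odds =
      std::log((1.0 - pi_prior) / std::max(pi_prior, 1e-300));
  int kept = 0;

  for (int it = 0; it < n_iter; ++it) {
    // overall mean
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += e[i] + mu;
    double mu_new = R::rnorm(r / n, std::sqrt(s2e / n));
    double dmu = mu_new - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = mu_new;

    // SNP effects
    for (int j = 0; j < p; ++j) {
      const double d = dj[j];
      if (d <= 0.0) { w[j] = 0.0; delta[j] = 0; continue; }
      double old_contrib = w[j];
      if (mode == 0 && delta[j] == 0) old_contrib = 0.0;
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += Z(i, j) * e[i];
      rhs += d * old_contrib;

      double new_w, v_small, v_large;
      int new_delta;
      if (mode == 0) {
        // spike at zero vs slab N(0, s2w)
        v_small = d * s2e;                    // rhs variance, effect zero
        v_large = d * s2e + d * d * s2w;      // rhs variance, effect present
        double log_odds = (pi_prior <= 0.0) ? R_PosInf :
            log_prior_odds + 0.5 * (std::log(v_small / v_large) +
                                    rhs * rhs * (1.0 / v_small - 1.0 / v_large));
        double pr1 = (log_odds > 0) ? 1.0 / (1.0 + std::exp(-log_odds))
                                    : std::exp(log_odds) / (1.0 + std::exp(log_odds));
        new_delta = (R::unif_rand() < pr1) ? 1 : 0;
        if (new_delta == 1) {
          double lam = s2e / s2w;
          double post_var = s2e / (d + lam);
          new_w = R::rnorm(rhs / (d + lam), std::sqrt(post_var));
        } else {
          new_w = 0.0;
        }
      } else {
        // small variance s2w / c vs large variance s2w
        double s2_small = s2w / c_ratio;
        v_small = d * s2e + d * d * s2_small;
        v_large = d * s2e + d * d * s2w;
        double log_odds =
            log_prior_odds + 0.5 * (std::log(v_small / v_large) +
                                    rhs * rhs * (1.0 / v_small - 1.0 / v_large));
        double pr1 = (log_odds > 0) ? 1.0 / (1.0 + std::exp(-log_odds))
                                    : std::exp(log_odds) / (1.0 + std::exp(log_odds));
        new_delta = (R::unif_rand() < pr1) ? 1 : 0;
        double s2_use = new_delta ? s2w : s2_small;
        double lam = s2e / s2_use;
        double post_var = s2e / (d + lam);
        new_w = R::rnorm(rhs / (d + lam), std::sqrt(post_var));
      }
      double diff = old_contrib - new_w;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] += Z(i, j) * diff;
      w[j] = new_w;
      delta[j] = new_delta;
    }

    // common SNP variance (scaled-inverse-chi-square full conditional)
    double ss = 0.0;
    int m = 0;
    if (mode == 0) {
      for (int j = 0; j < p; ++j)
        if (delta[j]) { ss += w[j] * w[j]; ++m; }
    } else {
      for (int j = 0; j < p; ++j) {
        ss += w[j] * w[j] * (delta[j] ? 1.0 : c_ratio);
        ++m;
      }
    }
    s2w = (ss + nu_w * s2_w) / R::rchisq(nu_w + m);

    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (sse + nu_e * s2_e) / R::rchisq(nu_e + n);

    if (!R_finite(s2e) || !R_finite(s2w) || s2e <= 0.0)
      stop("divergent chain at iteration %d: sigma_e2=%g sigma_w2=%g",
           it + 1, s2e, s2w);

    if (it >= burn_in && ((it - burn_in) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < p; ++j) {
        keep_w(kept, j) = (mode == 0 && !delta[j]) ? 0.0 : w[j];
        keep_delta(kept, j) = delta[j];
      }
      keep_mu[kept] = mu;
      keep_s2e[kept] = s2e;
      keep_s2w[kept] = s2w;
      ++kept;
    }
  }

  return List::create(_["w"] = keep_w, _["delta"] = keep_delta,
                      _["mu"] = keep_mu, _["sigma_e2"] = keep_s2e,
                      _["sigma_w2"] = keep_s2w, _["n_kept"] = kept);
}
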