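#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian(mu, lambda) draw (Michael, Schucany & Haas); uses R's RNG
// so results are reproducible under set.seed().
static double rinvgauss(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + (mu * mu * y) / (2.0 * lambda) -
             (mu / (2.0 * lambda)) *
                 std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  double u = unif_rand();
  if (u <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Park & Casella (2008) Bayesian Lasso Gibbs sampler with coordinate-wise
// updates of the marker effects. X must be column-centered; y is used as-is
// (the intercept mu is sampled). Returns posterior means of mu and beta over
// the kept iterations, plus chains of lambda2 and sigma2 for diagnostics.
// [[Rcpp::export(name = ".bl_gibbs")]]
List bl_gibbs(NumericMatrix X, NumericVector y, int n_iter, int burn_in,
              double r_hyper, double rho_hyper) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> x2(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    x2[j] = s;
  }
  double ybar = mean(y);
  double mu = ybar;
  double sigma2 = var(y);
  if (sigma2 <= 0) stop("zero-variance response");
  // start at dimension-scaled strong shrinkage (as practical samplers do):
  // with weak initial shrinkage and m >> n the chain can drift into a
  // degenerate interpolation mode (sigma2 -> 0) that null data never escape
  double lambda2 = std::max(10.0, (double)m);
  std::vector<double> beta(m, 0.0), tau2(m, 2.0 / lambda2);
  // residual e = y - mu - X beta
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  std::vector<double> beta_sum(m, 0.0);
  double mu_sum = 0.0;
  int kept = 0;
  NumericVector lambda2_chain(n_iter), sigma2_chain(n_iter);
  // RNG state is managed by the Rcpp attributes wrapper (RNGScope)
  for (int it = 0; it < n_iter; ++it) {
    // beta_j | rest : N(mean, var), coordinate-wise with running residual
    const double* xp = X.begin();
    for (int j = 0; j < m; ++j, xp += n) {
      if (x2[j] <= 0.0) { beta[j] = 0.0; continue; }
      double bj = beta[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += xp[i] * e[i];
      rhs += x2[j] * bj;  // add back x_j' x_j beta_j excluded from the residual
      double prec = x2[j] + 1.0 / tau2[j];
      double mean_j = rhs / prec;
      double new_b = mean_j + norm_rand() * std::sqrt(sigma2 / prec);
      double diff = new_b - bj;
      if (diff != 0.0)
        for (int i = 0; i < n; ++i) e[i] -= xp[i] * diff;
      beta[j] = new_b;
    }
    // mu | rest (X is centered, so mu is conditionally independent of beta)
    {
      double resid_mean = 0.0;
      for (int i = 0; i < n; ++i) resid_mean += e[i] + mu;
      resid_mean /= n;  // mean of y - X beta
      double new_mu = resid_mean + norm_rand() * std::sqrt(sigma2 / n);
      double dmu = new_mu - mu;
      for (int i = 0; i < n; ++i) e[i] -= dmu;
      mu = new_mu;
    }
    // 1/tau2_j | rest ~ InvGaussian(sqrt(lambda2 sigma2 / beta_j^2), lambda2)
    double sum_tau2 = 0.0, sum_b2_tau = 0.0;
    for (int j = 0; j < m; ++j) {
      double b2 = beta[j] * beta[j];
      if (b2 < 1e-300) b2 = 1e-300;
      double mu_ig = std::sqrt(lambda2 * sigma2 / b2);
      double inv_tau2 = rinvgauss(mu_ig, lambda2);
      tau2[j] = 1.0 / inv_tau2;
      sum_tau2 += tau2[j];
      sum_b2_tau += b2 / tau2[j];
    }
    // lambda2 | rest ~ Gamma(r + m, rho + sum(tau2)/2)
    lambda2 = R::rgamma(r_hyper + m, 1.0 / (rho_hyper + sum_tau2 / 2.0));
    // sigma2 | rest ~ Inv-Gamma((n - 1 + m)/2, ||e||^2/2 + sum(b^2/tau2)/2)
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    double shape = 0.5 * (n - 1 + m);
    double rate = 0.5 * (sse + sum_b2_tau);
    sigma2 = rate / R::rgamma(shape, 1.0);
    lambda2_chain[it] = lambda2;
    sigma2_chain[it] = sigma2;
    if (it >= burn_in) {
      ++kept;
      mu_sum += mu;
      for (int j = 0; j < m; ++j) beta_sum[j] += beta[j];
    }
  }
  NumericVector beta_mean(m);
  for (int j = 0; j < m; ++j) beta_mean[j] = beta_sum[j] / kept;
  return List::create(_["mu"] = mu_sum / kept, _["beta"] = beta_mean,
                      _["lambda2"] = lambda2_chain, _["sigma2"] = sigma2_chain);
}
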