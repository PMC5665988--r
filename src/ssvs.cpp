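// Dirac-spike / normal-slab Gibbs sampler for sparse linear regression.
//
// Model: y_i ~ N(x_i beta + alpha, sigma^2)
//        beta_j ~ pi * delta_0 + (1 - pi) * N(0, psi_j^2)
//        pi ~ Beta(1, 1); psi_j^-2 ~ Ga(aPsi, bPsi);
//        sigma^-2 ~ Ga(aSigma, bSigma); alpha ~ N(mu0, sigma0^2)
//
// Each beta_j update marginalizes beta_j analytically to get the posterior
// inclusion odds (slab vs spike marginal-likelihood ratio times prior odds),
// then draws from the slab's conditional normal when included. Uses R's RNG
// so runs are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".ssvsGibbs")]]
List ssvsGibbs(NumericMatrix X, NumericVector y, int iterations, int burnin,
               double aPsi, double bPsi, double aSigma, double bSigma,
               double mu0, double sigma02) {
  const int n = X.nrow(), p = X.ncol();
  const int kept = iterations - burnin;

  std::vector<double> colSS(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    colSS[j] = s;
  }

  std::vector<double> beta(p, 0.0), psi2(p, 1.0);
  double ybar = 0.0, yvar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  for (int i = 0; i < n; ++i) yvar += (y[i] - ybar) * (y[i] - ybar);
  yvar = (n > 1) ? yvar / (n - 1) : 1.0;
  double alpha = ybar, sigma2 = (yvar > 0 ? yvar : 1.0), piSpike = 0.5;

  std::vector<double> r(n);  // residual y - alpha - X beta
  for (int i = 0; i < n; ++i) r[i] = y[i] - alpha;

  NumericMatrix betaDraws(kept, p);
  NumericVector alphaDraws(kept), sigma2Draws(kept), piDraws(kept);

  for (int it = 0; it < iterations; ++it) {
    // beta_j sweep
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0)
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * beta[j];
      double xr = 0.0;
      for (int i = 0; i < n; ++i) xr += X(i, j) * r[i];
      double v = 1.0 / (colSS[j] / sigma2 + 1.0 / psi2[j]);
      double m = v * xr / sigma2;
      // log marginal-likelihood ratio slab/spike
      double logBF = 0.5 * std::log(v / psi2[j]) + 0.5 * m * m / v;
      double logOdds = std::log1p(-piSpike) - std::log(piSpike) + logBF;
      double pIncl = 1.0 / (1.0 + std::exp(-logOdds));
      if (unif_rand() < pIncl) {
        beta[j] = m + std::sqrt(v) * norm_rand();
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * beta[j];
      } else {
        beta[j] = 0.0;
      }
    }
    // pi | beta : Beta(1 + #zero, 1 + #nonzero)
    int nz = 0;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) ++nz;
    piSpike = R::rbeta(1.0 + (p - nz), 1.0 + nz);
    // psi_j^-2: posterior when beta_j in the slab, prior otherwise
    for (int j = 0; j < p; ++j) {
      double prec = (beta[j] != 0.0)
          ? R::rgamma(aPsi + 0.5, 1.0 / (bPsi + 0.5 * beta[j] * beta[j]))
          : R::rgamma(aPsi, 1.0 / bPsi);
      psi2[j] = 1.0 / prec;
    }
    // sigma^-2
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    sigma2 = 1.0 / R::rgamma(aSigma + 0.5 * n, 1.0 / (bSigma + 0.5 * rss));
    // alpha
    for (int i = 0; i < n; ++i) r[i] += alpha;
    double rsum = 0.0;
    for (int i = 0; i < n; ++i) rsum += r[i];
    double va = 1.0 / (n / sigma2 + 1.0 / sigma02);
    double ma = va * (rsum / sigma2 + mu0 / sigma02);
    alpha = ma + std::sqrt(va) * norm_rand();
    for (int i = 0; i < n; ++i) r[i] -= alpha;

    if (!std::isfinite(alpha) || !std::isfinite(sigma2))
      stop("sampler diverged (non-finite draw) at iteration %d", it + 1);

    if (it >= burnin) {
      int k = it - burnin;
      for (int j = 0; j < p; ++j) betaDraws(k, j) = beta[j];
      alphaDraws[k] = alpha;
      sigma2Draws[k] = sigma2;
      piDraws[k] = piSpike;
    }
  }

  return List::create(_["beta"] = betaDraws, _["alpha"] = alphaDraws,
                      _["sigma2"] = sigma2Draws, _["pi"] = piDraws);
}
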