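// compiled kernels for the volatility and correlation recursions: these are
// evaluated hundreds of times per fit inside the optimizer, so the O(T)
// loops live here.

#include <Rcpp.h>
using namespace Rcpp;

// conditional variances sigma^2_t = omega + alpha * y^2_{t-1} + beta * sigma^2_{t-1}
// [[Rcpp::export(name = ".garch_sigma2_c")]]
NumericVector garch_sigma2_c(double omega, double alpha, double beta,
                             NumericVector x2, double s2_init) {
  int n = x2.size();
  NumericVector s2(n);
  s2[0] = s2_init;
  for (int t = 1; t < n; ++t) {
    s2[t] = omega + alpha * x2[t - 1] + beta * s2[t - 1];
  }
  return s2;
}

// Gaussian QML negative log-likelihood of a GARCH(1,1) series
// [[Rcpp::export(name = ".garch_nll_c")]]
double garch_nll_c(double omega, double alpha, double beta,
                   NumericVector x2, double s2_init) {
  int n = x2.size();
  const double l2pi = std::log(2.0 * M_PI);
  double s2 = s2_init, nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (t > 0) s2 = omega + alpha * x2[t - 1] + beta * s2;
    if (!(s2 > 0.0) || !std::isfinite(s2)) return 1e10;
    nll += 0.5 * (l2pi + std::log(s2) + x2[t] / s2);
  }
  return std::isfinite(nll) ? nll : 1e10;
}

// dynamic correlation path r_t of the bivariate DCC recursion,
// Q_1 = Qbar, Q_t = (1-th1-th2) Qbar + th1 eps_{t-1} eps_{t-1}' + th2 Q_{t-1}
// [[Rcpp::export(name = ".dcc_rt_c")]]
NumericVector dcc_rt_c(double th1, double th2, NumericVector qb,
                       NumericVector p11, NumericVector p12, NumericVector p22) {
  int n = p11.size();
  double base = 1.0 - th1 - th2;
  double q11 = qb[0], q12 = qb[1], q22 = qb[2];
  NumericVector r(n);
  r[0] = q12 / std::sqrt(q11 * q22);
  for (int t = 1; t < n; ++t) {
    q11 = base * qb[0] + th1 * p11[t - 1] + th2 * q11;
    q12 = base * qb[1] + th1 * p12[t - 1] + th2 * q12;
    q22 = base * qb[2] + th1 * p22[t - 1] + th2 * q22;
    r[t] = q12 / std::sqrt(q11 * q22);
  }
  return r;
}

// second-stage (correlation) negative quasi-log-likelihood
// [[Rcpp::export(name = ".dcc_nll_c")]]
double dcc_nll_c(double th1, double th2, NumericVector qb,
                 NumericVector p11, NumericVector p12, NumericVector p22) {
  int n = p11.size();
  double base = 1.0 - th1 - th2;
  double q11 = qb[0], q12 = qb[1], q22 = qb[2];
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (t > 0) {
      q11 = base * qb[0] + th1 * p11[t - 1] + th2 * q11;
      q12 = base * qb[1] + th1 * p12[t - 1] + th2 * q12;
      q22 = base * qb[2] + th1 * p22[t - 1] + th2 * q22;
    }
    double r = q12 / std::sqrt(q11 * q22);
    double r2 = r * r;
    if (r2 > 1.0 - 1e-12) r2 = 1.0 - 1e-12;
    double denom = 1.0 - r2;
    nll += 0.5 * (std::log(denom) +
                  (p11[t] + p22[t] - 2.0 * r * p12[t]) / denom -
                  p11[t] - p22[t]);
    if (!std::isfinite(nll)) return 1e10;
  }
  return nll;
}
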