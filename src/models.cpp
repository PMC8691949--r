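// Fast trajectory + likelihood evaluation used inside the optimisation
// loops. Mirrors the reference R implementations in R/models.R exactly;
// equality is asserted in the test suite. Invalid trajectories (non-positive
// precisions in the hierarchical filters) return NA, which the fitting code
// maps to -Inf log-joint.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sgm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// model codes: 0 = RW (param = alpha), 1 = HGF2 (param = omega2),
// 2 = HGF3 (param = kappa2)
// fixed: v0, mu2_0, sigma2_0, mu3_0, sigma3_0, omega2, omega3
// [[Rcpp::export]]
NumericVector traj_cpp(IntegerVector u, int model, double param,
                       NumericVector fixed) {
  int n = u.size();
  NumericVector v(n);
  if (model == 0) {
    double vk = fixed[0];
    for (int k = 0; k < n; ++k) {
      v[k] = vk;
      vk += param * (u[k] - vk);
    }
  } else if (model == 1) {
    double m2 = fixed[1], s2 = fixed[2];
    double eo = std::exp(param);
    for (int k = 0; k < n; ++k) {
      double muhat1 = sgm(m2);
      v[k] = muhat1;
      double pihat2 = 1.0 / (s2 + eo);
      double pi2 = pihat2 + muhat1 * (1.0 - muhat1);
      if (!std::isfinite(pi2) || pi2 <= 0.0) {
        v[0] = NA_REAL; return v;
      }
      m2 += (u[k] - muhat1) / pi2;
      s2 = 1.0 / pi2;
    }
  } else if (model == 2) {
    double m2 = fixed[1], s2 = fixed[2], m3 = fixed[3], s3 = fixed[4];
    double om2 = fixed[5], om3 = fixed[6], ka = param;
    double eo3 = std::exp(om3);
    for (int k = 0; k < n; ++k) {
      double muhat1 = sgm(m2);
      v[k] = muhat1;
      double expt = std::exp(ka * m3 + om2);
      double pihat2 = 1.0 / (s2 + expt);
      double pi2 = pihat2 + muhat1 * (1.0 - muhat1);
      if (!std::isfinite(pi2) || pi2 <= 0.0) { v[0] = NA_REAL; return v; }
      double m2new = m2 + (u[k] - muhat1) / pi2;
      double da2 = (1.0 / pi2 + (m2new - m2) * (m2new - m2)) * pihat2 - 1.0;
      double pihat3 = 1.0 / (s3 + eo3);
      double w2 = expt * pihat2;
      double pi3 = pihat3 + 0.5 * ka * ka * w2 * (w2 + (2.0 * w2 - 1.0) * da2);
      if (!std::isfinite(pi3) || pi3 <= 0.0) { v[0] = NA_REAL; return v; }
      m3 += 0.5 * (1.0 / pi3) * ka * w2 * da2;
      s3 = 1.0 / pi3;
      m2 = m2new;
      s2 = 1.0 / pi2;
    }
  } else {
    stop("unknown model code");
  }
  return v;
}

// Total response-model log-likelihood for one parameter setting; returns
// NA when the trajectory is invalid.
// [[Rcpp::export]]
double loglik_cpp(IntegerVector u, IntegerVector y, int model, double param,
                  double zeta, NumericVector fixed) {
  NumericVector v = traj_cpp(u, model, param, fixed);
  if (NumericVector::is_na(v[0])) return NA_REAL;
  int n = v.size();
  double ll = 0.0;
  const double eps = 1e-8;
  for (int k = 0; k < n; ++k) {
    double vk = v[k];
    if (vk < eps) vk = eps;
    if (vk > 1.0 - eps) vk = 1.0 - eps;
    // p(y=1) = logistic(zeta * logit(v))
    double p = sgm(zeta * (std::log(vk) - std::log1p(-vk)));
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    ll += y[k] ? std::log(p) : std::log1p(-p);
  }
  return ll;
}
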