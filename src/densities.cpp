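#include <Rcpp.h>
#include "densities.h"
using namespace Rcpp;

// Log density of the location-scale Student-t.
double st_lpdf(double y, double nu, double mu, double sigma) {
  double z = (y - mu) / sigma;
  return R::lgammafn(0.5 * (nu + 1.0)) - R::lgammafn(0.5 * nu)
    - 0.5 * std::log(nu * M_PI) - std::log(sigma)
    - 0.5 * (nu + 1.0) * std::log1p(z * z / nu);
}

// Log density of the exGaussian (normal(mu, sigma) + exponential(rate lambda)).
// Written with pnorm on the log scale so the lambda^2 sigma^2 / 2 term cancels
// against the Gaussian tail for large lambda instead of overflowing.
double exg_lpdf(double t, double mu, double sigma, double lambda) {
  double z = (t - mu - lambda * sigma * sigma) / sigma;
  return std::log(lambda) + lambda * (mu - t)
    + 0.5 * lambda * lambda * sigma * sigma
    + R::pnorm(z, 0.0, 1.0, 1, 1);
}

// Log density of the von Mises distribution; kappa = 0 is the circular uniform.
double vm_lpdf(double theta, double mu, double kappa) {
  // bessel_i with expon.scaled = TRUE returns exp(-kappa) * I0(kappa)
  double log_i0 = std::log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
  return kappa * std::cos(theta - mu) - std::log(2.0 * M_PI) - log_i0;
}

// Log density of a normal truncated to [lo, hi] (normalising constant included).
double tnorm_lpdf(double x, double m, double s, double lo, double hi) {
  if (x < lo || x > hi) return R_NegInf;
  double z = R::pnorm(hi, m, s, 1, 0) - R::pnorm(lo, m, s, 1, 0);
  if (z <= 0) return R_NegInf;
  return R::dnorm(x, m, s, 1) - std::log(z);
}

// Log density of Beta(p * tau, (1 - p) * tau) at x.
double rbeta_lpdf(double x, double p, double tau) {
  return R::dbeta(x, p * tau, (1.0 - p) * tau, 1);
}

// [[Rcpp::export(name = ".st_lpdf_cpp")]]
NumericVector st_lpdf_cpp(NumericVector y, double nu, double mu, double sigma) {
  int n = y.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st_lpdf(y[i], nu, mu, sigma);
  return out;
}

// [[Rcpp::export(name = ".exg_lpdf_cpp")]]
NumericVector exg_lpdf_cpp(NumericVector t, double mu, double sigma, double lambda) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = exg_lpdf(t[i], mu, sigma, lambda);
  return out;
}

// [[Rcpp::export(name = ".vm_lpdf_cpp")]]
NumericVector vm_lpdf_cpp(NumericVector theta, double mu, double kappa) {
  int n = theta.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = vm_lpdf(theta[i], mu, kappa);
  return out;
}

// [[Rcpp::export(name = ".tnorm_lpdf_cpp")]]
NumericVector tnorm_lpdf_cpp(NumericVector x, double m, double s,
                             double lo, double hi) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tnorm_lpdf(x[i], m, s, lo, hi);
  return out;
}
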