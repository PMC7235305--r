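#include <Rcpp.h>
#include "densities.h"
using namespace Rcpp;

// Componentwise adaptive random-walk Metropolis. Each scalar coordinate keeps
// its own log proposal scale, adapted toward a 0.44 acceptance rate during
// warmup with a diminishing Robbins-Monro step, then frozen for sampling.

static const double TARGET_ACC = 0.44;
static const double NU_LO = 0.1, NU_HI = 1e4;   // support guard for t-test nu
static const double TAU_HI = 1000.0;            // support guard for beta tau
static const double KAPPA_HI = 1e4;             // support guard for von Mises

static inline bool mh_accept(double log_ratio) {
  if (!std::isfinite(log_ratio)) return false;
  if (log_ratio >= 0) return true;
  return unif_rand() < std::exp(log_ratio);
}

static inline void adapt(double &ls, bool acc, int k) {
  double eta = std::pow((double)k + 1.0, -0.6);
  ls += eta * ((acc ? 1.0 : 0.0) - TARGET_ACC);
  if (ls < -12.0) ls = -12.0;
  if (ls > 6.0) ls = 6.0;
}

// Log prior density on the natural scale.
// family: 0 none/flat, 1 uniform(a,b), 2 normal(mean a, sd b),
//         3 gamma(shape a, rate b), 4 beta(a, b)
static double prior_lp(int fam, double a, double b, double x) {
  switch (fam) {
  case 1: return (x < a || x > b) ? R_NegInf : -std::log(b - a);
  case 2: return R::dnorm(x, a, b, 1);
  case 3: return R::dgamma(x, a, 1.0 / b, 1);
  case 4: return R::dbeta(x, a, b, 1);
  default: return 0.0;
  }
}

static inline double prior_row(const NumericMatrix &pr, int row, double x) {
  return prior_lp((int)pr(row, 0), pr(row, 1), pr(row, 2), x);
}

// ---------------------------------------------------------------------------
// t-test: scaled/shifted Student-t likelihood; params mu, sigma, nu.
// Unconstrained state: (mu, log sigma, log nu). Default priors are flat on
// mu, log sigma and log nu with nu restricted to [NU_LO, NU_HI].
// ---------------------------------------------------------------------------

struct TTestPost {
  const NumericVector &y;
  const NumericMatrix &prior;
  double operator()(const std::vector<double> &u) const {
    double mu = u[0], sigma = std::exp(u[1]), nu = std::exp(u[2]);
    if (nu < NU_LO || nu > NU_HI) return R_NegInf;
    double lp = 0.0;
    // user priors act on the natural scale; positive params add the log
    // Jacobian of exp() so the prior really is the stated natural-scale one
    if ((int)prior(0, 0) != 0) lp += prior_row(prior, 0, mu);
    if ((int)prior(1, 0) != 0) lp += prior_row(prior, 1, sigma) + u[1];
    if ((int)prior(2, 0) != 0) lp += prior_row(prior, 2, nu) + u[2];
    if (!std::isfinite(lp)) return R_NegInf;
    for (int i = 0; i < y.size(); ++i) lp += st_lpdf(y[i], nu, mu, sigma);
    return lp;
  }
};

// [[Rcpp::export(name = ".chain_ttest_cpp")]]
NumericMatrix chain_ttest_cpp(NumericVector y, int warmup, int iter,
                              NumericVector init, NumericMatrix prior) {
  TTestPost post{y, prior};
  std::vector<double> u(3);
  u[0] = init[0];
  u[1] = std::log(init[1]);
  u[2] = std::log(init[2]);
  double cur = post(u);
  if (!std::isfinite(cur)) stop("non-finite log posterior at initial values");
  std::vector<double> ls(3, -1.0);
  std::vector<int> cnt(3, 0);
  NumericMatrix out(iter, 3);
  for (int it = 0; it < warmup + iter; ++it) {
    for (int c = 0; c < 3; ++c) {
      double old = u[c];
      u[c] = old + std::exp(ls[c]) * norm_rand();
      double prop = post(u);
      bool acc = mh_accept(prop - cur);
      if (acc) cur = prop; else u[c] = old;
      if (it < warmup) adapt(ls[c], acc, ++cnt[c]);
    }
    if (it >= warmup) {
      out(it - warmup, 0) = u[0];
      out(it - warmup, 1) = std::exp(u[1]);
      out(it - warmup, 2) = std::exp(u[2]);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Shared machinery for the three hierarchical models. Subject-level scalar
// parameters are updated one coordinate block at a time against the subject's
// own data likelihood plus its group-level prior term; group-level parameters
// are updated against the sum of those prior terms.
// ---------------------------------------------------------------------------

// hierarchical normal prior term, optionally truncated to (0, inf)
static inline double hnorm_lp(double v, double m, double s, bool pos) {
  double lp = R::dnorm(v, m, s, 1);
  if (pos) lp -= R::pnorm(0.0, m, s, 0, 1); // - log P(X > 0)
  return lp;
}

// ---------------------------------------------------------------------------
// Reaction times: exGaussian subject likelihood, subject params
// (mu_i, sigma_i, lambda_i); group params (mu_mu, sigma_mu, mu_sigma,
// sigma_sigma, mu_lambda, sigma_lambda), the sigma and lambda group normals
// truncated to positive support. prior: 6 x 3 group prior matrix.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".chain_exg_cpp")]]
NumericMatrix chain_exg_cpp(NumericVector t, IntegerVector subj, int n_subj,
                            int warmup, int iter,
                            NumericMatrix init_subj, NumericVector init_group,
                            NumericMatrix prior) {
  int n_obs = t.size();
  std::vector<std::vector<int> > idx(n_subj);
  for (int i = 0; i < n_obs; ++i) idx[subj[i]].push_back(i);

  // unconstrained subject state: mu, log sigma, log lambda
  NumericMatrix us(n_subj, 3);
  for (int i = 0; i < n_subj; ++i) {
    us(i, 0) = init_subj(i, 0);
    us(i, 1) = std::log(init_subj(i, 1));
    us(i, 2) = std::log(init_subj(i, 2));
  }
  // unconstrained group state: identity for means of mu, log for the rest
  std::vector<double> g(6);
  g[0] = init_group[0];
  for (int k = 1; k < 6; ++k) g[k] = std::log(init_group[k]);

  std::vector<double> gn(6); // natural scale
  auto to_nat = [&]() {
    gn[0] = g[0];
    for (int k = 1; k < 6; ++k) gn[k] = std::exp(g[k]);
  };
  to_nat();

  auto subj_ll = [&](int i, double mu, double sigma, double lambda) {
    double ll = 0.0;
    for (size_t j = 0; j < idx[i].size(); ++j)
      ll += exg_lpdf(t[idx[i][j]], mu, sigma, lambda);
    return ll;
  };
  auto hier_lp = [&](int j, double v) {
    if (j == 0) return hnorm_lp(v, gn[0], gn[1], false);
    if (j == 1) return hnorm_lp(v, gn[2], gn[3], true);
    return hnorm_lp(v, gn[4], gn[5], true);
  };

  std::vector<double> cll(n_subj);
  for (int i = 0; i < n_subj; ++i)
    cll[i] = subj_ll(i, us(i, 0), std::exp(us(i, 1)), std::exp(us(i, 2)));

  NumericMatrix ls_s(n_subj, 3);
  std::fill(ls_s.begin(), ls_s.end(), -1.0);
  IntegerMatrix cnt_s(n_subj, 3);
  std::vector<double> ls_g(6, -1.0);
  std::vector<int> cnt_g(6, 0);
  double ls_t = -1.0;
  int cnt_t = 0;

  int n_par = 6 + 3 * n_subj;
  NumericMatrix out(iter, n_par);

  for (int it = 0; it < warmup + iter; ++it) {
    // subject updates
    for (int j = 0; j < 3; ++j) {
      for (int i = 0; i < n_subj; ++i) {
        double old = us(i, j);
        double cand = old + std::exp(ls_s(i, j)) * norm_rand();
        double mu = (j == 0) ? cand : us(i, 0);
        double sg = (j == 1) ? std::exp(cand) : std::exp(us(i, 1));
        double lm = (j == 2) ? std::exp(cand) : std::exp(us(i, 2));
        double v_new = (j == 0) ? cand : ((j == 1) ? sg : lm);
        double v_old = (j == 0) ? old : std::exp(old);
        double ll_new = subj_ll(i, mu, sg, lm);
        double delta = ll_new - cll[i]
          + hier_lp(j, v_new) - hier_lp(j, v_old)
          + ((j > 0) ? (cand - old) : 0.0); // Jacobian of exp()
        bool acc = mh_accept(delta);
        if (acc) { us(i, j) = cand; cll[i] = ll_new; }
        if (it < warmup) adapt(ls_s(i, j), acc, ++cnt_s(i, j));
      }
    }
    // group updates
    for (int k = 0; k < 6; ++k) {
      int j = k / 2; // which subject-level parameter this group pair governs
      double old = g[k];
      double cand = old + std::exp(ls_g[k]) * norm_rand();
      double delta = 0.0;
      g[k] = cand; to_nat();
      for (int i = 0; i < n_subj; ++i) {
        double v = (j == 0) ? us(i, 0) : std::exp(us(i, j));
        delta += hier_lp(j, v);
      }
      delta += prior_row(prior, k, gn[k]);
      g[k] = old; to_nat();
      for (int i = 0; i < n_subj; ++i) {
        double v = (j == 0) ? us(i, 0) : std::exp(us(i, j));
        delta -= hier_lp(j, v);
      }
      delta -= prior_row(prior, k, gn[k]);
      if (k > 0) delta += cand - old; // flat positive prior: exp() Jacobian
      bool acc = mh_accept(delta);
      if (acc) { g[k] = cand; to_nat(); }
      if (it < warmup) adapt(ls_g[k], acc, ++cnt_g[k]);
    }
    // translation move: shift mu_mu and every mu_i together. The
    // hierarchical prior terms are invariant, only the data likelihood and
    // the flat hyperprior change; this decouples mixing of the location
    // from the (possibly tiny) group scale, which otherwise pins the
    // subject parameters when few subjects inform the hierarchy.
    {
      double delta = std::exp(ls_t) * norm_rand();
      double acc_lp = 0.0;
      std::vector<double> ll_new(n_subj);
      for (int i = 0; i < n_subj; ++i) {
        ll_new[i] = subj_ll(i, us(i, 0) + delta, std::exp(us(i, 1)),
                            std::exp(us(i, 2)));
        acc_lp += ll_new[i] - cll[i];
      }
      acc_lp += prior_row(prior, 0, gn[0] + delta) - prior_row(prior, 0, gn[0]);
      bool acc = mh_accept(acc_lp);
      if (acc) {
        for (int i = 0; i < n_subj; ++i) { us(i, 0) += delta; cll[i] = ll_new[i]; }
        g[0] += delta; to_nat();
      }
      if (it < warmup) adapt(ls_t, acc, ++cnt_t);
    }
    if (it >= warmup) {
      int r = it - warmup;
      for (int k = 0; k < 6; ++k) out(r, k) = gn[k];
      for (int i = 0; i < n_subj; ++i) {
        out(r, 6 + i) = us(i, 0);
        out(r, 6 + n_subj + i) = std::exp(us(i, 1));
        out(r, 6 + 2 * n_subj + i) = std::exp(us(i, 2));
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hierarchical linear model: per-subject intercept/slope/noise with group
// normals (noise group normal truncated positive). Subject likelihood uses
// per-subject sufficient statistics, so a likelihood evaluation is O(1).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".chain_linear_cpp")]]
NumericMatrix chain_linear_cpp(NumericVector x, NumericVector y,
                               IntegerVector subj, int n_subj,
                               int warmup, int iter,
                               NumericMatrix init_subj, NumericVector init_group,
                               NumericMatrix prior) {
  int n_obs = x.size();
  std::vector<double> N(n_subj, 0), Sx(n_subj, 0), Sy(n_subj, 0),
    Sxx(n_subj, 0), Sxy(n_subj, 0), Syy(n_subj, 0);
  for (int i = 0; i < n_obs; ++i) {
    int s = subj[i];
    N[s] += 1.0; Sx[s] += x[i]; Sy[s] += y[i];
    Sxx[s] += x[i] * x[i]; Sxy[s] += x[i] * y[i]; Syy[s] += y[i] * y[i];
  }

  NumericMatrix us(n_subj, 3); // alpha, beta, log sigma
  for (int i = 0; i < n_subj; ++i) {
    us(i, 0) = init_subj(i, 0);
    us(i, 1) = init_subj(i, 1);
    us(i, 2) = std::log(init_subj(i, 2));
  }
  std::vector<double> g(6), gn(6);
  g[0] = init_group[0]; g[1] = std::log(init_group[1]);
  g[2] = init_group[2]; g[3] = std::log(init_group[3]);
  g[4] = std::log(init_group[4]); g[5] = std::log(init_group[5]);
  auto to_nat = [&]() {
    gn[0] = g[0]; gn[1] = std::exp(g[1]);
    gn[2] = g[2]; gn[3] = std::exp(g[3]);
    gn[4] = std::exp(g[4]); gn[5] = std::exp(g[5]);
  };
  to_nat();

  auto subj_ll = [&](int i, double a, double b, double s) {
    double sse = Syy[i] - 2.0 * a * Sy[i] - 2.0 * b * Sxy[i]
      + 2.0 * a * b * Sx[i] + a * a * N[i] + b * b * Sxx[i];
    if (sse < 0) sse = 0; // guard tiny negative from cancellation
    return -0.5 * N[i] * std::log(2.0 * M_PI) - N[i] * std::log(s)
      - sse / (2.0 * s * s);
  };
  auto hier_lp = [&](int j, double v) {
    if (j == 0) return hnorm_lp(v, gn[0], gn[1], false);
    if (j == 1) return hnorm_lp(v, gn[2], gn[3], false);
    return hnorm_lp(v, gn[4], gn[5], true);
  };

  std::vector<double> cll(n_subj);
  for (int i = 0; i < n_subj; ++i)
    cll[i] = subj_ll(i, us(i, 0), us(i, 1), std::exp(us(i, 2)));

  NumericMatrix ls_s(n_subj, 3);
  std::fill(ls_s.begin(), ls_s.end(), -1.0);
  IntegerMatrix cnt_s(n_subj, 3);
  std::vector<double> ls_g(6, -1.0);
  std::vector<int> cnt_g(6, 0);
  double ls_t[2] = {-1.0, -1.0};
  int cnt_t[2] = {0, 0};

  NumericMatrix out(iter, 6 + 3 * n_subj);
  for (int it = 0; it < warmup + iter; ++it) {
    for (int j = 0; j < 3; ++j) {
      for (int i = 0; i < n_subj; ++i) {
        double old = us(i, j);
        double cand = old + std::exp(ls_s(i, j)) * norm_rand();
        double a = (j == 0) ? cand : us(i, 0);
        double b = (j == 1) ? cand : us(i, 1);
        double s = (j == 2) ? std::exp(cand) : std::exp(us(i, 2));
        double v_new = (j == 2) ? s : cand;
        double v_old = (j == 2) ? std::exp(old) : old;
        double ll_new = subj_ll(i, a, b, s);
        double delta = ll_new - cll[i]
          + hier_lp(j, v_new) - hier_lp(j, v_old)
          + ((j == 2) ? (cand - old) : 0.0);
        bool acc = mh_accept(delta);
        if (acc) { us(i, j) = cand; cll[i] = ll_new; }
        if (it < warmup) adapt(ls_s(i, j), acc, ++cnt_s(i, j));
      }
    }
    for (int k = 0; k < 6; ++k) {
      int j = k / 2;
      double old = g[k];
      double cand = old + std::exp(ls_g[k]) * norm_rand();
      double delta = 0.0;
      g[k] = cand; to_nat();
      for (int i = 0; i < n_subj; ++i) {
        double v = (j == 2) ? std::exp(us(i, 2)) : us(i, j);
        delta += hier_lp(j, v);
      }
      delta += prior_row(prior, k, gn[k]);
      g[k] = old; to_nat();
      for (int i = 0; i < n_subj; ++i) {
        double v = (j == 2) ? std::exp(us(i, 2)) : us(i, j);
        delta -= hier_lp(j, v);
      }
      delta -= prior_row(prior, k, gn[k]);
      if (k == 1 || k == 3 || k == 4 || k == 5) delta += cand - old;
      bool acc = mh_accept(delta);
      if (acc) { g[k] = cand; to_nat(); }
      if (it < warmup) adapt(ls_g[k], acc, ++cnt_g[k]);
    }
    // translation moves: jointly shift (mu_a, all alpha_i) and
    // (mu_b, all beta_i); hierarchical terms cancel, see the exGaussian
    // sampler for the rationale
    for (int j = 0; j < 2; ++j) {
      double delta = std::exp(ls_t[j]) * norm_rand();
      double acc_lp = 0.0;
      std::vector<double> ll_new(n_subj);
      for (int i = 0; i < n_subj; ++i) {
        double a = us(i, 0) + (j == 0 ? delta : 0.0);
        double b = us(i, 1) + (j == 1 ? delta : 0.0);
        ll_new[i] = subj_ll(i, a, b, std::exp(us(i, 2)));
        acc_lp += ll_new[i] - cll[i];
      }
      int k = 2 * j;
      acc_lp += prior_row(prior, k, gn[k] + delta) - prior_row(prior, k, gn[k]);
      bool acc = mh_accept(acc_lp);
      if (acc) {
        for (int i = 0; i < n_subj; ++i) { us(i, j) += delta; cll[i] = ll_new[i]; }
        g[k] += delta; to_nat();
      }
      if (it < warmup) adapt(ls_t[j], acc, ++cnt_t[j]);
    }
    if (it >= warmup) {
      int r = it - warmup;
      for (int k = 0; k < 6; ++k) out(r, k) = gn[k];
      for (int i = 0; i < n_subj; ++i) {
        out(r, 6 + i) = us(i, 0);
        out(r, 6 + n_subj + i) = us(i, 1);
        out(r, 6 + 2 * n_subj + i) = std::exp(us(i, 2));
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Success rates: Bernoulli subject likelihood via success/trial counts,
// Beta(p * tau, (1 - p) * tau) hierarchical prior on subject rates. Subject
// rates sampled on the logit scale; group p on the logit scale with a Beta
// prior (default Beta(1, 1)); tau on the log scale, flat on (0, TAU_HI].
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".chain_success_cpp")]]
NumericMatrix chain_success_cpp(IntegerVector succ, IntegerVector trials,
                                int warmup, int iter,
                                NumericVector init_p, double init_gp,
                                double init_tau, NumericMatrix prior) {
  int n_subj = succ.size();
  std::vector<double> u(n_subj); // logit p_i
  for (int i = 0; i < n_subj; ++i)
    u[i] = std::log(init_p[i]) - std::log1p(-init_p[i]);
  double gp = std::log(init_gp) - std::log1p(-init_gp); // logit group p
  double gt = std::log(init_tau);                       // log tau

  auto inv_logit = [](double z) { return 1.0 / (1.0 + std::exp(-z)); };
  auto subj_ll = [&](int i, double p) {
    return succ[i] * std::log(p) + (trials[i] - succ[i]) * std::log1p(-p);
  };

  std::vector<double> ls_s(n_subj, -1.0), cll(n_subj);
  std::vector<int> cnt_s(n_subj, 0);
  double ls_gp = -1.0, ls_gt = -1.0, ls_t = -1.0;
  int cnt_gp = 0, cnt_gt = 0, cnt_t = 0;
  for (int i = 0; i < n_subj; ++i) cll[i] = subj_ll(i, inv_logit(u[i]));

  NumericMatrix out(iter, 2 + n_subj);
  for (int it = 0; it < warmup + iter; ++it) {
    double p = inv_logit(gp), tau = std::exp(gt);
    for (int i = 0; i < n_subj; ++i) {
      double old = u[i];
      double cand = old + std::exp(ls_s[i]) * norm_rand();
      double pi_new = inv_logit(cand), pi_old = inv_logit(old);
      double ll_new = subj_ll(i, pi_new);
      double delta = ll_new - cll[i]
        + rbeta_lpdf(pi_new, p, tau) - rbeta_lpdf(pi_old, p, tau)
        + std::log(pi_new) + std::log1p(-pi_new)   // logit Jacobian
        - std::log(pi_old) - std::log1p(-pi_old);
      bool acc = mh_accept(delta);
      if (acc) { u[i] = cand; cll[i] = ll_new; }
      if (it < warmup) adapt(ls_s[i], acc, ++cnt_s[i]);
    }
    { // group p
      double old = gp;
      double cand = old + std::exp(ls_gp) * norm_rand();
      double p_new = inv_logit(cand), p_old = inv_logit(old);
      double delta = prior_row(prior, 0, p_new) - prior_row(prior, 0, p_old)
        + std::log(p_new) + std::log1p(-p_new)
        - std::log(p_old) - std::log1p(-p_old);
      for (int i = 0; i < n_subj; ++i) {
        double pi = inv_logit(u[i]);
        delta += rbeta_lpdf(pi, p_new, tau) - rbeta_lpdf(pi, p_old, tau);
      }
      bool acc = mh_accept(delta);
      if (acc) gp = cand;
      if (it < warmup) adapt(ls_gp, acc, ++cnt_gp);
    }
    { // group tau
      double old = gt;
      double cand = old + std::exp(ls_gt) * norm_rand();
      double delta;
      if (std::exp(cand) > TAU_HI) {
        delta = R_NegInf;
      } else {
        double p_cur = inv_logit(gp);
        double t_new = std::exp(cand), t_old = std::exp(old);
        delta = prior_row(prior, 1, t_new) - prior_row(prior, 1, t_old)
          + cand - old; // flat positive prior: exp() Jacobian
        for (int i = 0; i < n_subj; ++i) {
          double pi = inv_logit(u[i]);
          delta += rbeta_lpdf(pi, p_cur, t_new) - rbeta_lpdf(pi, p_cur, t_old);
        }
      }
      bool acc = mh_accept(delta);
      if (acc) gt = cand;
      if (it < warmup) adapt(ls_gt, acc, ++cnt_gt);
    }
    { // translation move on the logit scale: shift group p and all p_i
      double delta = std::exp(ls_t) * norm_rand();
      double tau_c = std::exp(gt);
      double p_new = inv_logit(gp + delta), p_old = inv_logit(gp);
      double acc_lp = prior_row(prior, 0, p_new) - prior_row(prior, 0, p_old)
        + std::log(p_new) + std::log1p(-p_new)
        - std::log(p_old) - std::log1p(-p_old);
      std::vector<double> ll_new(n_subj);
      for (int i = 0; i < n_subj; ++i) {
        double pi_new = inv_logit(u[i] + delta), pi_old = inv_logit(u[i]);
        ll_new[i] = subj_ll(i, pi_new);
        acc_lp += ll_new[i] - cll[i]
          + rbeta_lpdf(pi_new, p_new, tau_c) - rbeta_lpdf(pi_old, p_old, tau_c)
          + std::log(pi_new) + std::log1p(-pi_new)
          - std::log(pi_old) - std::log1p(-pi_old);
      }
      bool acc = mh_accept(acc_lp);
      if (acc) {
        for (int i = 0; i < n_subj; ++i) { u[i] += delta; cll[i] = ll_new[i]; }
        gp += delta;
      }
      if (it < warmup) adapt(ls_t, acc, ++cnt_t);
    }
    if (it >= warmup) {
      int r = it - warmup;
      out(r, 0) = inv_logit(gp);
      out(r, 1) = std::exp(gt);
      for (int i = 0; i < n_subj; ++i) out(r, 2 + i) = inv_logit(u[i]);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Truncated-normal color component on [lo, hi]: params (m, s). The mean is
// restricted to within two component ranges of the interval and s to ten
// ranges: flat priors otherwise make the uniform limit (m -> -inf, s -> inf)
// an improper plateau. Sufficient statistics make evaluations O(1) in n.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".chain_tnorm_cpp")]]
NumericMatrix chain_tnorm_cpp(NumericVector xdat, double lo, double hi,
                              int warmup, int iter, NumericVector init) {
  int n = xdat.size();
  double Sx = 0, Sxx = 0;
  for (int i = 0; i < n; ++i) { Sx += xdat[i]; Sxx += xdat[i] * xdat[i]; }
  double range = hi - lo;
  double m = init[0], lsg = std::log(init[1]);
  auto lpost = [&](double mm, double u) {
    double s = std::exp(u);
    if (mm < lo - 2.0 * range || mm > hi + 2.0 * range) return R_NegInf;
    if (s > 10.0 * range) return R_NegInf;
    double z = R::pnorm(hi, mm, s, 1, 0) - R::pnorm(lo, mm, s, 1, 0);
    if (z <= 0) return R_NegInf;
    double sse = Sxx - 2.0 * mm * Sx + n * mm * mm;
    return -n * std::log(s) - 0.5 * n * std::log(2.0 * M_PI)
      - sse / (2.0 * s * s) - n * std::log(z);
  };
  double cur = lpost(m, lsg);
  if (!std::isfinite(cur)) stop("non-finite log posterior at initial values");
  double ls[2] = {-1.0, -1.0};
  int cnt[2] = {0, 0};
  NumericMatrix out(iter, 2);
  for (int it = 0; it < warmup + iter; ++it) {
    for (int c = 0; c < 2; ++c) {
      double old = (c == 0) ? m : lsg;
      double cand = old + std::exp(ls[c]) * norm_rand();
      double prop = (c == 0) ? lpost(cand, lsg) : lpost(m, cand);
      bool acc = mh_accept(prop - cur);
      if (acc) { cur = prop; if (c == 0) m = cand; else lsg = cand; }
      if (it < warmup) adapt(ls[c], acc, ++cnt[c]);
    }
    if (it >= warmup) {
      out(it - warmup, 0) = m;
      out(it - warmup, 1) = std::exp(lsg);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// von Mises hue component: params (mu in [0, 2pi), kappa > 0). mu is updated
// by a symmetric random walk wrapped on the circle under a flat circular
// prior; kappa is flat positive on (0, KAPPA_HI] via a log transform.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".chain_vm_cpp")]]
NumericMatrix chain_vm_cpp(NumericVector theta, int warmup, int iter,
                           NumericVector init) {
  int n = theta.size();
  double C = 0, S = 0;
  for (int i = 0; i < n; ++i) { C += std::cos(theta[i]); S += std::sin(theta[i]); }
  double mu = init[0], lk = std::log(init[1]);
  auto lpost = [&](double mm, double u) {
    double kappa = std::exp(u);
    if (kappa > KAPPA_HI) return R_NegInf;
    double log_i0 = std::log(R::bessel_i(kappa, 0.0, 2.0)) + kappa;
    return kappa * (C * std::cos(mm) + S * std::sin(mm))
      - n * (std::log(2.0 * M_PI) + log_i0)
      + u; // flat positive prior on kappa: exp() Jacobian
  };
  double cur = lpost(mu, lk);
  if (!std::isfinite(cur)) stop("non-finite log posterior at initial values");
  double ls[2] = {-1.0, -1.0};
  int cnt[2] = {0, 0};
  const double TWO_PI = 2.0 * M_PI;
  NumericMatrix out(iter, 2);
  for (int it = 0; it < warmup + iter; ++it) {
    { // mu, wrapped proposal
      double step = mu + std::exp(ls[0]) * norm_rand();
      double cand = step - TWO_PI * std::floor(step / TWO_PI);
      double prop = lpost(cand, lk);
      bool acc = mh_accept(prop - cur);
      if (acc) { cur = prop; mu = cand; }
      if (it < warmup) adapt(ls[0], acc, ++cnt[0]);
    }
    { // log kappa
      double cand = lk + std::exp(ls[1]) * norm_rand();
      double prop = lpost(mu, cand);
      bool acc = mh_accept(prop - cur);
      if (acc) { cur = prop; lk = cand; }
      if (it < warmup) adapt(ls[1], acc, ++cnt[1]);
    }
    if (it >= warmup) {
      out(it - warmup, 0) = mu;
      out(it - warmup, 1) = std::exp(lk);
    }
  }
  return out;
}
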