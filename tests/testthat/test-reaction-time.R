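test_that("exGaussian log density matches closed form and normalizes", {
  # ln(0.5 * exp(0.5) * erfc(1/sqrt(2)))
  closed <- log(0.5) + 0.5 + log(2 * pnorm(-1))
  expect_equal(exgaussian_log_density(0, 0, 1, 1), closed, tolerance = 1e-7)
  expect_lt(abs(closed - (-1.34102)), 1e-4)

  # quadrature of the density integrates to 1
  for (pars in list(c(0, 1, 1), c(0.3, 0.05, 8), c(-2, 0.5, 0.2))) {
    f <- function(t) exp(exgaussian_log_density(t, pars[1], pars[2], pars[3]))
    q <- integrate(f, pars[1] - 10 * pars[2],
                   pars[1] + 10 * pars[2] + 30 / pars[3],
                   rel.tol = 1e-9)
    expect_lt(abs(q$value - 1), 1e-6)
  }

  # normal limit as the exponential tail vanishes
  expect_lt(abs(exgaussian_log_density(0, 0, 1, 1e4) - (-0.5 * log(2 * pi))),
            1e-2)
  expect_error(exgaussian_log_density(0, 0, -1, 1), class = "bpsy_domain_error")
  expect_error(exgaussian_log_density(0, 0, 1, 0), class = "bpsy_domain_error")
})

sim_rt <- function(n_subj, trials, mu_mu, sigma_mu, mu_sigma, mu_lambda,
                   sigma_lambda, seed) {
  set.seed(seed)
  mu_i <- rnorm(n_subj, mu_mu, sigma_mu)
  sg_i <- abs(rnorm(n_subj, mu_sigma, mu_sigma / 4)) + 1e-3
  lm_i <- abs(rnorm(n_subj, mu_lambda, sigma_lambda)) + 0.1
  s <- rep(seq_len(n_subj), each = trials)
  t <- rnorm(n_subj * trials, mu_i[s], sg_i[s]) + rexp(n_subj * trials, lm_i[s])
  list(t = pmax(t, 1e-3), s = s)
}

test_that("group mean recovery: HDI covers mu_mu + 1/mu_lambda", {
  d <- sim_rt(20, 100, mu_mu = 0.3, sigma_mu = 0.05, mu_sigma = 0.05,
              mu_lambda = 5, sigma_lambda = 1, seed = 31)
  f <- fit_quick(b_reaction_time, d$t, d$s, seed = 31)
  h <- compute_hdi(rt_group_mean_draws(f), 0.95)
  expect_lte(h$lower, 0.5); expect_gte(h$upper, 0.5)

  # the reported group mean tracks the empirical grand mean
  rep <- summarize_fit(f)
  expect_lt(abs(mean(rt_group_mean_draws(f)) - mean(d$t)), 0.02)
})

test_that("rt_group_mean_draws is the element-wise E = mu_mu + 1/mu_lambda", {
  d <- sim_rt(5, 30, 0.3, 0.05, 0.05, 5, 1, seed = 32)
  f <- fit_quick(b_reaction_time, d$t, d$s, seed = 32)
  expect_equal(rt_group_mean_draws(f),
               extract_group_draws(f, "mu_mu") +
                 1 / extract_group_draws(f, "mu_lambda"))
})

test_that("subject indexing must be contiguous from 1", {
  d <- sim_rt(3, 20, 0.3, 0.05, 0.05, 5, 1, seed = 33)
  err <- tryCatch(b_reaction_time(d$t, d$s + 21L), condition = identity)
  expect_s3_class(err, "bpsy_validation_error")
  expect_match(conditionMessage(err), "1 to n")
  expect_error(b_reaction_time(c(0.5, -0.2), c(1, 1)),
               class = "bpsy_validation_error")
})

test_that("identical seeds give identical fits", {
  d <- sim_rt(4, 25, 0.3, 0.05, 0.05, 5, 1, seed = 34)
  f1 <- b_reaction_time(d$t, d$s, chains = 2, warmup = 100, iter = 100,
                        seed = 77)
  f2 <- b_reaction_time(d$t, d$s, chains = 2, warmup = 100, iter = 100,
                        seed = 77)
  expect_identical(f1$draws$values, f2$draws$values)
})

test_that("sparse subjects shrink toward the group mean", {
  set.seed(35)
  base <- sim_rt(15, 80, 0.30, 0.03, 0.05, 5, 0.5, seed = 35)
  # subject 16: only 5 trials, drawn far above the group
  extra_t <- 0.8 + rexp(5, 5)
  t <- c(base$t, extra_t)
  s <- c(base$s, rep(16L, 5))
  f <- fit_quick(b_reaction_time, t, s, seed = 35)
  raw_mean <- mean(extra_t) - 1 / 5  # raw mu estimate ~ mean - 1/lambda
  post_mu16 <- mean(extract_subject_draws(f, "mu", 16))
  group_mu <- mean(extract_group_draws(f, "mu_mu"))
  # posterior lies between the subject's raw estimate and the group mean,
  # strictly closer to the group than the raw estimate is
  expect_lt(abs(post_mu16 - group_mu), abs(mean(extra_t) - group_mu))
})

test_that("normally distributed data are accommodated (large lambda)", {
  set.seed(36)
  n_subj <- 10; trials <- 60
  s <- rep(seq_len(n_subj), each = trials)
  t <- rnorm(n_subj * trials, 1.0, 0.1)
  f <- fit_quick(b_reaction_time, t, s, seed = 36)
  h <- compute_hdi(rt_group_mean_draws(f), 0.95)
  expect_lte(h$lower, 1.0); expect_gte(h$upper, 1.0)
})
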