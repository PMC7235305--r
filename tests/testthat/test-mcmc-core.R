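test_that("prior construction and log densities behave per family", {
  expect_equal(prior_log_density(bprior("flat"), c(-1e6, 0, 1e6)), c(0, 0, 0))
  u <- bprior("uniform", c(0, 1))
  expect_identical(prior_log_density(u, 1.5), -Inf)
  expect_equal(prior_log_density(u, 0.3), 0)
  expect_equal(prior_log_density(bprior("normal", c(0, 1)), 0),
               -0.5 * log(2 * pi), tolerance = 1e-10)
  expect_equal(prior_log_density(bprior("gamma", c(2, 3)), 1.2),
               dgamma(1.2, 2, rate = 3, log = TRUE))
  expect_equal(prior_log_density(bprior("beta", c(2, 5)), 0.3),
               dbeta(0.3, 2, 5, log = TRUE))
  expect_error(bprior("normal", c(0, -1)), class = "bpsy_validation_error")
  expect_error(bprior("uniform", c(2, 1)), class = "bpsy_validation_error")
  expect_error(bprior("flat", c(1, 2)), class = "bpsy_validation_error")
})

test_that("text priors parse like their constructors", {
  p <- parse_prior("normal(120, 20)")
  expect_equal(p$family, "normal")
  expect_equal(p$params, c(120, 20))
  expect_equal(parse_prior("flat")$family, "flat")
  expect_error(parse_prior("cauchy(0,1)"), class = "bpsy_validation_error")
  expect_error(parse_prior("normal(a,b)"), class = "bpsy_validation_error")
})

bernoulli_spec <- function() {
  model_spec(
    parameters = list(list(name = "p", support = "interval",
                           lower = 0, upper = 1)),
    log_lik = function(theta, data) {
      sum(data) * log(theta[["p"]]) + sum(1 - data) * log(1 - theta[["p"]])
    },
    priors = list(p = bprior("beta", c(1, 1))))
}

test_that("generic sampler reproduces the Beta-Bernoulli conjugate posterior", {
  data <- c(rep(1, 7), rep(0, 3))
  dm <- sample_posterior(bernoulli_spec(), data,
                         sampler_settings(4, 500, 500, seed = 11))
  x <- as.vector(dm$values[, , 1])
  # conjugate Beta(8, 4): mean 2/3, sd sqrt(8*4/(12^2*13))
  mc_se <- sd(x) / sqrt(effective_sample_size(dm, "p"))
  expect_lt(abs(mean(x) - 8 / 12), 3 * mc_se)
  expect_lt(abs(sd(x) - sqrt(8 * 4 / (144 * 13))), 3 * mc_se)
  expect_true(all(x > 0 & x < 1))
})

test_that("generic sampler reproduces the normal-mean conjugate posterior", {
  set.seed(12)
  y <- rnorm(100, 3, 1)
  spec <- model_spec(
    parameters = list(list(name = "mu", support = "real")),
    log_lik = function(theta, data) sum(dnorm(data, theta[["mu"]], 1, log = TRUE)),
    init = function(data, chain) c(mu = mean(data)))
  dm <- sample_posterior(spec, y, sampler_settings(4, 500, 500, seed = 13))
  x <- as.vector(dm$values[, , 1])
  mc_se <- sd(x) / sqrt(effective_sample_size(dm, "mu"))
  expect_lt(abs(mean(x) - mean(y)), 3 * mc_se)          # posterior N(ybar, 1/10)
  expect_lt(abs(sd(x) - 0.1), 3 * mc_se + 0.01)
})

test_that("sampling is deterministic in the seed and respects supports", {
  data <- c(rep(1, 3), rep(0, 2))
  s <- sampler_settings(2, 200, 200, seed = 99)
  d1 <- sample_posterior(bernoulli_spec(), data, s)
  d2 <- sample_posterior(bernoulli_spec(), data, s)
  expect_identical(d1$values, d2$values)

  # positive-support parameter stays strictly positive
  spec <- model_spec(
    parameters = list(list(name = "sigma", support = "positive")),
    log_lik = function(theta, data) sum(dnorm(data, 0, theta[["sigma"]],
                                              log = TRUE)))
  dm <- sample_posterior(spec, rnorm(50, 0, 2),
                         sampler_settings(2, 200, 200, seed = 5))
  expect_true(all(dm$values > 0))
})

test_that("settings and model specs validate their invariants", {
  expect_error(sampler_settings(chains = 0), class = "bpsy_validation_error")
  expect_error(sampler_settings(iter = 0), class = "bpsy_validation_error")
  expect_error(model_spec(list(), function(...) 0),
               class = "bpsy_validation_error")
  expect_error(model_spec(list(list(name = "x", support = "weird")),
                          function(...) 0),
               class = "bpsy_validation_error")
  expect_error(
    model_spec(list(list(name = "x", support = "real")), function(...) 0,
               priors = list(zeta = bprior("flat"))),
    class = "bpsy_lookup_error")
})
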