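test_that("HDI handles degenerate, normal and exponential draws", {
  h <- compute_hdi(rep(3, 1000), 0.95)
  expect_equal(c(h$lower, h$upper), c(3, 3))

  set.seed(101)
  h <- compute_hdi(rnorm(1e5), 0.95)
  expect_lt(abs(h$lower - (-1.96)), 0.05)
  expect_lt(abs(h$upper - 1.96), 0.05)

  h <- compute_hdi(rexp(1e5), 0.95)
  expect_lt(abs(h$lower - 0), 0.05)
  expect_lt(abs(h$upper - (-log(0.05))), 0.05)
})

test_that("HDI equals the exhaustive shortest-window oracle", {
  set.seed(102)
  for (rep in 1:40) {
    n <- sample(2:1000, 1)
    x <- switch(1 + rep %% 4,
                rnorm(n),
                rexp(n),
                sample(1:10, n, replace = TRUE),     # heavy ties
                c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 8)))
    mass <- runif(1, 0.05, 0.99)
    h <- compute_hdi(x, mass)
    expect_identical(c(h$lower, h$upper), hdi_oracle(x, mass))
  }
})

test_that("HDI mass monotonicity holds on unimodal draws", {
  set.seed(103)
  for (rep in 1:20) {
    x <- rnorm(500)
    h1 <- compute_hdi(x, 0.5)
    h2 <- compute_hdi(x, 0.8)
    h3 <- compute_hdi(x, 0.95)
    expect_gte(h1$lower, h2$lower); expect_lte(h1$upper, h2$upper)
    expect_gte(h2$lower, h3$lower); expect_lte(h2$upper, h3$upper)
  }
})

test_that("HDI validates its inputs", {
  expect_error(compute_hdi(1), class = "bpsy_validation_error")
  expect_error(compute_hdi(c(1, 2), mass = 1), class = "bpsy_validation_error")
  expect_error(compute_hdi(c(1, 2), mass = 0), class = "bpsy_validation_error")
})

test_that("split R-hat is ~1 for converged chains, large for separated ones", {
  set.seed(104)
  dm <- draw_matrix(array(rnorm(4 * 1000), c(4, 1000, 1)), "x")
  r <- split_rhat(dm, "x")
  expect_gt(r, 0.99); expect_lt(r, 1.01)

  # two chains centred 10 apart: B dominates; check against the direct
  # formula evaluated on the split halves
  dm2 <- draw_matrix(aperm(array(c(rnorm(1000), rnorm(1000, 10)),
                                 c(1000, 2, 1)), c(2, 1, 3)), "x")
  r2 <- split_rhat(dm2, "x")
  expect_gt(r2, 1.5)
  ch <- matrix(dm2$values[, , 1], nrow = 2)
  halves <- rbind(ch[, 1:500], ch[, 501:1000])
  W <- mean(apply(halves, 1, var))
  B <- 500 * var(rowMeans(halves))
  expect_equal(r2, sqrt(((500 - 1) * W / 500 + B / 500) / W))
})

test_that("split R-hat is affine invariant and rejects constant chains", {
  set.seed(105)
  arr <- array(rnorm(4 * 500), c(4, 500, 1))
  dm <- draw_matrix(arr, "x")
  dm2 <- draw_matrix(arr * -3.7 + 42, "x")
  expect_equal(split_rhat(dm, "x"), split_rhat(dm2, "x"), tolerance = 1e-10)
  expect_error(split_rhat(draw_matrix(array(1, c(2, 100, 1)), "x"), "x"),
               class = "bpsy_degenerate_error")
})

test_that("effective sample size matches IID and AR(1) benchmarks", {
  set.seed(106)
  dm <- draw_matrix(array(rnorm(4000), c(4, 1000, 1)), "x")
  ess <- effective_sample_size(dm, "x")
  expect_gte(ess, 3200); expect_lte(ess, 4800)

  rho <- 0.9
  n <- 10000
  z <- numeric(n); z[1] <- rnorm(1)
  for (i in 2:n) z[i] <- rho * z[i - 1] + sqrt(1 - rho^2) * rnorm(1)
  dm1 <- draw_matrix(array(z, c(1, n, 1)), "x")
  ess1 <- effective_sample_size(dm1, "x")
  expected <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(ess1 - expected) / expected, 0.3)

  # negative lag-1 autocorrelation: capped at the total draw count
  alt <- draw_matrix(array(rep(c(1, -1), 500) + rnorm(1000, 0, 1e-3),
                           c(1, 1000, 1)), "x")
  expect_equal(effective_sample_size(alt, "x"), 1000)
  expect_error(effective_sample_size(draw_matrix(array(2, c(2, 50, 1)), "x"),
                                     "x"),
               class = "bpsy_degenerate_error")
})

test_that("summary report satisfies its definitional identities", {
  f <- fit_quick(b_ttest, rnorm(300, 5, 2), seed = 42)
  rep <- summarize_fit(f)
  expect_named(rep, c("parameter", "mean", "se_mean", "sd", "q2.5", "q97.5",
                      "n_eff", "rhat"))
  expect_equal(rep$se_mean, rep$sd / sqrt(rep$n_eff), tolerance = 1e-12)
  expect_true(all(rep$n_eff > 0))
  mu_row <- rep[rep$parameter == "mu", ]
  expect_lt(abs(mu_row$mean - 5), 3 * mu_row$se_mean + 0.15)

  # round trip: extracted draws reproduce the report mean
  expect_equal(mean(extract_group_draws(f, "mu")), mu_row$mean)
  expect_error(summarize_fit(draw_matrix(array(1, c(2, 100, 1)), "x")),
               class = "bpsy_degenerate_error")
})

test_that("draw extraction respects shapes and errors", {
  f <- fit_quick(b_ttest, rnorm(100), seed = 7)
  expect_length(extract_group_draws(f, "mu"), quick$chains * quick$iter)
  err <- tryCatch(extract_group_draws(f, "zeta"), condition = identity)
  expect_s3_class(err, "bpsy_lookup_error")
  expect_match(conditionMessage(err), "mu")   # lists available names

  set.seed(8)
  s <- rep(1:5, each = 30)
  t <- 0.3 + abs(rnorm(150, 0, 0.05)) + rexp(150, 10)
  fr <- fit_quick(b_reaction_time, t, s, seed = 8)
  expect_length(extract_subject_draws(fr, "mu", 1), quick$chains * quick$iter)
  expect_error(extract_subject_draws(fr, "mu", 6), class = "bpsy_index_error")
  expect_error(extract_subject_draws(f, "mu", 1),
               class = "bpsy_unsupported_error")
})

test_that("summary report serializes with the conventional header", {
  f <- fit_quick(b_ttest, rnorm(100, 2), seed = 9)
  path <- tempfile(fileext = ".csv")
  write_summary(summarize_fit(f), path)
  hdr <- read.csv(path, check.names = FALSE)
  expect_named(hdr, c("parameter", "mean", "se_mean", "sd", "2.5%", "97.5%",
                      "n_eff", "Rhat"))
})
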