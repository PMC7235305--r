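test_that("index-aligned pairwise comparison matches the worked example", {
  a <- c(123, 128, 121, 137, 110)
  b <- c(118, 126, 119, 110, 122)
  cmp <- compare_means_pair(a, b)
  expect_identical(cmp$pairs$p_greater, 0.8)
  expect_identical(cmp$pairs$p_smaller, 0.2)
})

test_that("identical draws are fully equal under any ROPE", {
  a <- rnorm(100)
  cmp <- compare_means_pair(a, a, rope = c(-0.2, 0.2))
  expect_identical(cmp$pairs$p_equal, 1)
  expect_identical(cmp$pairs$p_smaller, 0)
  expect_identical(cmp$pairs$p_greater, 0)
  expect_equal(c(cmp$pairs$hdi_lower, cmp$pairs$hdi_upper), c(0, 0))
})

test_that("pairwise probabilities equal the naive enumeration oracle", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(c(10, 100, 1000, 10000), 1)
    a <- rnorm(n)
    b <- rnorm(n, 0.2)
    if (rep %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) } # force ties
    rope <- if (rep %% 2 == 0) c(-0.3, 0.3) else NULL
    cmp <- compare_means_pair(a, b, rope = rope)
    o <- pair_oracle(a, b, rope)
    expect_identical(cmp$pairs$p_smaller, o$p_lt)
    expect_identical(cmp$pairs$p_greater, o$p_gt)
    expect_identical(cmp$pairs$p_equal, o$p_eq)
  }
})

test_that("probabilities sum to one and mirror under argument swap", {
  set.seed(72)
  a <- round(rnorm(500), 1); b <- round(rnorm(500), 1)
  for (rope in list(NULL, c(-0.1, 0.1))) {
    ab <- compare_means_pair(a, b, rope = rope)$pairs
    ba <- compare_means_pair(b, a, rope = rope)$pairs
    tot <- ab$p_smaller + ab$p_greater + ifelse(is.na(ab$p_equal), 0, ab$p_equal)
    expect_lt(abs(tot - 1), 1e-12)
    expect_identical(ab$p_smaller, ba$p_greater)
    expect_identical(ab$p_greater, ba$p_smaller)
    expect_equal(c(ab$hdi_lower, ab$hdi_upper),
                 -c(ba$hdi_upper, ba$hdi_lower))
  }
})

test_that("comparison probabilities are invariant under positive affine maps", {
  set.seed(73)
  a <- rnorm(1000); b <- rnorm(1000, 0.3)
  c0 <- compare_means_pair(a, b)
  c1 <- compare_means_pair(3 * a + 7, 3 * b + 7)
  expect_identical(c0$pairs$p_greater, c1$pairs$p_greater)
})

test_that("multi-group extremes match enumeration and tie-splitting", {
  cmp <- compare_means_multi(list(1, 2, 3))
  expect_identical(cmp$extremes$p_largest, c(0, 0, 1))
  expect_identical(cmp$extremes$p_smallest, c(1, 0, 0))

  set.seed(74)
  sets <- replicate(5, round(rnorm(1000), 1), simplify = FALSE)
  cmp <- compare_means_multi(sets)
  o <- extremes_oracle(sets)
  expect_equal(cmp$extremes$p_largest, o$p_largest, tolerance = 1e-12)
  expect_equal(cmp$extremes$p_smallest, o$p_smallest, tolerance = 1e-12)
  expect_lt(abs(sum(cmp$extremes$p_largest) - 1), 1e-12)
  expect_lt(abs(sum(cmp$extremes$p_smallest) - 1), 1e-12)

  # two identical sets in a 3-group comparison split the tie
  x <- rnorm(100)
  cmp2 <- compare_means_multi(list(x, x, x - 10))
  expect_identical(cmp2$extremes$p_largest[1:2], c(0.5, 0.5))
})

test_that("point comparisons behave like constant-vector pairs", {
  expect_identical(compare_mean_to_point(c(1, 2, 3), 0)$pairs$p_greater, 1)
  set.seed(75)
  cmp <- compare_mean_to_point(rnorm(1e5), 0)
  expect_gt(cmp$pairs$p_greater, 0.49); expect_lt(cmp$pairs$p_greater, 0.51)
  cmp2 <- compare_mean_to_point(rep(2, 50), 2, rope = c(-0.1, 0.1))
  expect_identical(cmp2$pairs$p_equal, 1)
})

test_that("misaligned draw counts raise an alignment error", {
  expect_error(compare_means_pair(rnorm(10), rnorm(11)),
               class = "bpsy_alignment_error")
  expect_error(compare_means_multi(list(rnorm(10), rnorm(10), rnorm(9))),
               class = "bpsy_alignment_error")
})

test_that("hue comparisons wrap: rotation by 2*pi is an exact tie", {
  th <- runif(200, 0, 2 * pi)
  a <- th; attr(a, "circular") <- TRUE
  cmp <- compare_means_pair(a, th + 2 * pi, rope = c(-0.01, 0.01))
  expect_identical(cmp$pairs$p_equal, 1)
})

test_that("posterior predictive matches known parameter values", {
  f <- constant_fit("bpsy_ttest", "ttest", c("mu", "sigma", "nu"),
                    c(0, 1, 1e6), n = 2000)
  y <- posterior_predictive_draws(f, n_per_draw = 50, seed = 1)
  expect_lt(abs(mean(y)), 0.02)
  expect_lt(abs(sd(y) - 1) / 1, 0.02)

  fs <- constant_fit("bpsy_success_rate", "success_rate", c("p", "tau"),
                     c(0.7, 10), n = 2000)
  r <- posterior_predictive_draws(fs, n_per_draw = 50, seed = 2)
  expect_lt(abs(mean(r) - 0.7), 3 * sqrt(0.21 / length(r)) + 0.005)

  # determinism
  y2 <- posterior_predictive_draws(f, n_per_draw = 50, seed = 1)
  expect_identical(y, y2)
})

test_that("compare_distributions separates, ties and matches its oracle", {
  f0 <- constant_fit("bpsy_ttest", "ttest", c("mu", "sigma", "nu"),
                     c(0, 1, 100), n = 2000)
  f100 <- constant_fit("bpsy_ttest", "ttest", c("mu", "sigma", "nu"),
                       c(100, 1, 100), n = 2000)
  cmp <- compare_distributions(f0, f100, n_per_draw = 5, seed = 3)
  expect_gt(cmp$pairs$p_smaller, 0.999)

  tie <- compare_distributions(f0, f0, n_per_draw = 5, seed = 4)
  expect_lt(abs(tie$pairs$p_greater - 0.5), 0.02)

  # equals the naive oracle on the very vectors it generated
  a <- posterior_predictive_draws(f0, 5, seed = 3 + 1)
  b <- posterior_predictive_draws(f100, 5, seed = 3 + 2)
  o <- pair_oracle(a, b)
  expect_identical(cmp$pairs$p_smaller, o$p_lt)

  fs <- constant_fit("bpsy_success_rate", "success_rate", c("p", "tau"),
                     c(0.7, 10), n = 2000)
  expect_error(compare_distributions(f0, fs),
               class = "bpsy_compatibility_error")
})

test_that("mean_draws_of dispatches per model and enforces selectors", {
  f <- constant_fit("bpsy_ttest", "ttest", c("mu", "sigma", "nu"),
                    c(2, 1, 10), n = 10)
  expect_identical(mean_draws_of(f), rep(2, 10))

  frt <- constant_fit("bpsy_reaction_time", "reaction_time",
                      c("mu_mu", "sigma_mu", "mu_sigma", "sigma_sigma",
                        "mu_lambda", "sigma_lambda"),
                      c(0.3, 0.1, 0.05, 0.01, 5, 1), n = 10)
  expect_equal(mean_draws_of(frt), rep(0.5, 10))

  fl <- constant_fit("bpsy_linear", "linear",
                     c("mu_a", "sigma_a", "mu_b", "sigma_b", "mu_s", "sigma_s"),
                     c(1, 1, 2, 1, 3, 1), n = 10)
  expect_error(mean_draws_of(fl), class = "bpsy_selector_error")
  expect_identical(mean_draws_of(fl, par = "slope"), rep(2, 10))
})
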