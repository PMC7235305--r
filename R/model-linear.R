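#' Hierarchical Bayesian linear model for sequential tasks
#'
#' Each subject's responses follow `y = alpha[i] + beta[i] * x + eps`,
#' `eps ~ N(0, sigma[i])`, with group-level normal priors
#' `N(mu_a, sigma_a)` on the intercepts, `N(mu_b, sigma_b)` on the slopes
#' and `N(mu_s, sigma_s)` (truncated positive) on the residual scales.
#' The comparison currency is selectable: `"intercept"` (`mu_a` draws),
#' `"slope"` (`mu_b`) or `"sigma"` (`mu_s`), see [compare_means()].
#'
#' `x` is used exactly as given (no internal centering), so the intercept
#' keeps its subject-matter meaning at `x = 0`; pass centered `x` yourself
#' if you want a centered intercept.
#'
#' @param x independent variable (time, trial or question index) per
#'   observation.
#' @param y response per observation.
#' @param s integer subject index per observation, contiguous from 1 to n;
#'   every subject needs at least two distinct `x` values.
#' @param priors named list of priors for `mu_a`, `sigma_a`, `mu_b`,
#'   `sigma_b`, `mu_s`, `sigma_s`.
#' @param chains,warmup,iter,seed sampler settings, see [sampler_settings()].
#' @return An object of class `c("bpsy_linear", "bpsy_fit")`.
#' @export
b_linear <- function(x, y, s, priors = NULL, chains = 4, warmup = 1000,
                     iter = 1000, seed = NULL) {
  if (!is.numeric(x) || !is.numeric(y) || !length(x))
    stop_validation("'x' and 'y' must be non-empty numeric vectors")
  if (length(x) != length(y) || length(x) != length(s))
    stop_validation("'x', 'y' and 's' must have the same length")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("'x' and 'y' must be finite")
  s <- validate_subjects(s)
  n_subj <- max(s)
  for (i in seq_len(n_subj)) {
    xi <- x[s == i]
    if (length(xi) < 2L || length(unique(xi)) < 2L)
      stop_validation(sprintf(
        "subject %d needs at least 2 observations with distinct x values", i))
  }
  settings <- sampler_settings(chains, warmup, iter, seed)
  group_pars <- c("mu_a", "sigma_a", "mu_b", "sigma_b", "mu_s", "sigma_s")
  priors <- normalize_priors(priors, group_pars)
  pm <- prior_matrix(priors, group_pars)

  base <- t(vapply(seq_len(n_subj), function(i) {
    xi <- x[s == i]; yi <- y[s == i]
    cf <- stats::coef(stats::lm.fit(cbind(1, xi), yi))
    res <- yi - cf[1] - cf[2] * xi
    c(a = unname(cf[1]), b = unname(cf[2]),
      s = max(sqrt(mean(res^2)), 1e-3))
  }, c(a = 0, b = 0, s = 0)))
  scale_y <- max(sd(y), 1e-3)

  run_one <- function(chain) {
    init_subj <- base
    init_subj[, 1] <- base[, 1] + 0.1 * scale_y * rnorm(n_subj)
    init_subj[, 2] <- base[, 2] + 0.05 * scale_y * rnorm(n_subj)
    init_subj[, 3] <- base[, 3] * exp(0.1 * rnorm(n_subj))
    init_group <- c(mean(init_subj[, 1]),
                    max(sd(init_subj[, 1]), 0.05 * scale_y),
                    mean(init_subj[, 2]),
                    max(sd(init_subj[, 2]), 0.01 * scale_y),
                    max(mean(init_subj[, 3]), 1e-3),
                    max(sd(init_subj[, 3]), 0.05 * scale_y))
    .chain_linear_cpp(x, y, s - 1L, n_subj, settings$warmup, settings$iter,
                      init_subj, init_group, pm)
  }
  values <- run_chains(settings, run_one, 6L + 3L * n_subj)
  par_names <- c(group_pars,
                 sprintf("alpha[%d]", seq_len(n_subj)),
                 sprintf("beta[%d]", seq_len(n_subj)),
                 sprintf("sigma[%d]", seq_len(n_subj)))
  new_bfit("linear", "bpsy_linear", values, par_names,
           group_pars = group_pars,
           subject_pars = c("alpha", "beta", "sigma"),
           n_subjects = n_subj, data = list(x = x, y = y, s = s),
           settings = settings, priors = priors)
}
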