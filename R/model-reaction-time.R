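#' Log density of the exGaussian distribution
#'
#' The exponentially modified normal: the distribution of the sum of a
#' Normal(`mu`, `sigma`) and an independent Exponential with rate `lambda`.
#' Its right-skewed shape is the standard model for reaction times; its mean
#' is `mu + 1/lambda`. The evaluation is numerically stable (log-Gaussian
#' tail form), so very large `lambda` recovers the plain normal density.
#'
#' @param t numeric value(s) at which to evaluate.
#' @param mu normal component location.
#' @param sigma normal component scale, > 0.
#' @param lambda exponential component rate, > 0.
#' @return Log density, vectorized over `t`.
#' @export
#' @examples
#' exgaussian_log_density(0, mu = 0, sigma = 1, lambda = 1)
exgaussian_log_density <- function(t, mu, sigma, lambda) {
  if (!is.finite(sigma) || sigma <= 0) stop_domain("'sigma' must be > 0")
  if (!is.finite(lambda) || lambda <= 0) stop_domain("'lambda' must be > 0")
  .exg_lpdf_cpp(as.numeric(t), mu, sigma, lambda)
}

#' Hierarchical Bayesian reaction-time model
#'
#' Each subject's reaction times follow an exGaussian with subject-level
#' parameters `mu[i]`, `sigma[i]`, `lambda[i]`; the subject parameters are
#' tied together by group-level normal distributions: `N(mu_mu, sigma_mu)`
#' for `mu`, `N(mu_sigma, sigma_sigma)` for `sigma` and
#' `N(mu_lambda, sigma_lambda)` for `lambda`, the latter two truncated to
#' positive support (a normal on a rate or scale would otherwise put mass on
#' negative values). The group-level mean reaction time is reported as
#' `E = mu_mu + 1/mu_lambda` (see [rt_group_mean_draws()]), and those draws
#' are the comparison currency of the fit.
#'
#' @param t positive reaction times, in seconds.
#' @param s integer subject index per observation; subjects must be indexed
#'   contiguously from 1 to n.
#' @param priors named list of priors for the group-level parameters
#'   `mu_mu`, `sigma_mu`, `mu_sigma`, `sigma_sigma`, `mu_lambda`,
#'   `sigma_lambda`.
#' @param chains,warmup,iter,seed sampler settings, see [sampler_settings()].
#' @return An object of class `c("bpsy_reaction_time", "bpsy_fit")`.
#' @export
b_reaction_time <- function(t, s, priors = NULL, chains = 4, warmup = 1000,
                            iter = 1000, seed = NULL) {
  if (!is.numeric(t) || !length(t))
    stop_validation("'t' must be a non-empty numeric vector")
  if (length(t) != length(s))
    stop_validation("'t' and 's' must have the same length")
  if (anyNA(t) || any(!is.finite(t)) || any(t <= 0))
    stop_validation("reaction times must be finite and positive")
  s <- validate_subjects(s)
  n_subj <- max(s)
  settings <- sampler_settings(chains, warmup, iter, seed)
  group_pars <- c("mu_mu", "sigma_mu", "mu_sigma", "sigma_sigma",
                  "mu_lambda", "sigma_lambda")
  priors <- normalize_priors(priors, group_pars)
  pm <- prior_matrix(priors, group_pars)

  # moment-based subject inits: mean = mu + 1/lambda, split the spread
  # between the normal and exponential components
  glob_sd <- max(sd(t), 1e-3)
  base <- t(vapply(seq_len(n_subj), function(i) {
    ti <- t[s == i]
    m <- mean(ti)
    sdv <- if (length(ti) > 1L) max(sd(ti), 1e-3) else glob_sd
    c(mu = m - sdv / 2, sigma = sdv / 2, lambda = 2 / sdv)
  }, c(mu = 0, sigma = 0, lambda = 0)))

  run_one <- function(chain) {
    init_subj <- base
    init_subj[, 1] <- base[, 1] + glob_sd * 0.1 * rnorm(n_subj)
    init_subj[, 2] <- base[, 2] * exp(0.1 * rnorm(n_subj))
    init_subj[, 3] <- base[, 3] * exp(0.1 * rnorm(n_subj))
    init_group <- c(mean(init_subj[, 1]),
                    max(sd(init_subj[, 1]), 0.05 * glob_sd),
                    max(mean(init_subj[, 2]), 1e-3),
                    max(sd(init_subj[, 2]), 0.05 * glob_sd),
                    max(mean(init_subj[, 3]), 1e-3),
                    max(sd(init_subj[, 3]), 0.05 / glob_sd))
    .chain_exg_cpp(t, s - 1L, n_subj, settings$warmup, settings$iter,
                   init_subj, init_group, pm)
  }
  values <- run_chains(settings, run_one, 6L + 3L * n_subj)
  par_names <- c(group_pars,
                 sprintf("mu[%d]", seq_len(n_subj)),
                 sprintf("sigma[%d]", seq_len(n_subj)),
                 sprintf("lambda[%d]", seq_len(n_subj)))
  new_bfit("reaction_time", "bpsy_reaction_time", values, par_names,
           group_pars = group_pars,
           subject_pars = c("mu", "sigma", "lambda"),
           n_subjects = n_subj, data = list(t = t, s = s),
           settings = settings, priors = priors)
}

#' Group-level mean reaction-time draws
#'
#' The exGaussian mean is `mu + 1/lambda`; at the group level the model
#' reports `E = mu_mu + 1/mu_lambda`, computed element-wise over aligned
#' posterior draws. This vector is what [compare_means()] uses for
#' reaction-time fits.
#'
#' @param fit a [b_reaction_time()] fit.
#' @return Numeric vector of group-level mean draws.
#' @export
rt_group_mean_draws <- function(fit) {
  if (!inherits(fit, "bpsy_reaction_time"))
    stop_validation("'fit' must come from b_reaction_time()")
  mu <- extract_group_draws(fit, "mu_mu")
  lam <- extract_group_draws(fit, "mu_lambda")
  if (any(lam <= 0))
    bpsy_stop("non-positive mu_lambda draw: corrupted fit",
              "bpsy_internal_error")
  mu + 1 / lam
}
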