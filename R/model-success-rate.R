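#' Log density of the mean/concentration-parameterized Beta distribution
#'
#' `Beta(p * tau, (1 - p) * tau)`: `p` is the mean of the distribution and
#' `tau` its concentration (larger `tau`, tighter around `p`). This is the
#' hierarchical prior tying subject success rates to the group rate.
#'
#' @param x value(s) in (0, 1) at which to evaluate.
#' @param p mean, in (0, 1).
#' @param tau concentration, > 0.
#' @return Log density, vectorized over `x`.
#' @export
#' @examples
#' reparam_beta_log_density(0.5, p = 0.5, tau = 2) # Beta(1, 1): log(1) = 0
reparam_beta_log_density <- function(x, p, tau) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop_domain("'p' must be strictly inside (0, 1)")
  if (!is.finite(tau) || tau <= 0) stop_domain("'tau' must be > 0")
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    stop_domain("'x' must be strictly inside (0, 1)")
  dbeta(x, p * tau, (1 - p) * tau, log = TRUE)
}

#' Hierarchical Bayesian success-rate model
#'
#' Binary task outcomes are modeled per subject as Bernoulli with success
#' rate `p[i]`, and the subject rates share the hierarchical prior
#' `Beta(p * tau, (1 - p) * tau)` where `p` is the group-level success rate
#' and `tau` the concentration. The group `p` draws are the comparison
#' currency of the fit. By default `p` carries a Beta(1, 1) (uniform) prior
#' and `tau` a flat prior on (0, 1000].
#'
#' @param r binary outcomes (0/1) per observation.
#' @param s integer subject index per observation, contiguous from 1 to n.
#' @param priors named list of priors for `p` and `tau`.
#' @param chains,warmup,iter,seed sampler settings, see [sampler_settings()].
#' @return An object of class `c("bpsy_success_rate", "bpsy_fit")`.
#' @export
b_success_rate <- function(r, s, priors = NULL, chains = 4, warmup = 1000,
                           iter = 1000, seed = NULL) {
  if (!is.numeric(r) || !length(r))
    stop_validation("'r' must be a non-empty numeric vector")
  if (length(r) != length(s))
    stop_validation("'r' and 's' must have the same length")
  if (anyNA(r) || !all(r %in% c(0, 1)))
    stop_validation("outcomes must be binary (0/1); recode your data first")
  s <- validate_subjects(s)
  n_subj <- max(s)
  settings <- sampler_settings(chains, warmup, iter, seed)
  group_pars <- c("p", "tau")
  priors <- normalize_priors(priors, group_pars)
  if (is.null(priors$p)) priors$p <- bprior("beta", c(1, 1))
  pm <- prior_matrix(priors, group_pars)

  succ <- as.integer(tapply(r, s, sum))
  trials <- as.integer(tapply(r, s, length))
  run_one <- function(chain) {
    init_p <- plogis(qlogis((succ + 1) / (trials + 2)) + 0.2 * rnorm(n_subj))
    gp <- min(max(mean(init_p), 0.02), 0.98)
    .chain_success_cpp(succ, trials, settings$warmup, settings$iter,
                       init_p, gp, 10 * exp(0.3 * rnorm(1)), pm)
  }
  values <- run_chains(settings, run_one, 2L + n_subj)
  par_names <- c(group_pars, sprintf("p[%d]", seq_len(n_subj)))
  new_bfit("success_rate", "bpsy_success_rate", values, par_names,
           group_pars = group_pars, subject_pars = "p",
           n_subjects = n_subj, data = list(r = r, s = s),
           settings = settings, priors = priors)
}
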