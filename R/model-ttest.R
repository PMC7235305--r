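#' Log density of the scaled and shifted Student-t distribution
#'
#' The robust data distribution of the Bayesian t-test: a Student-t with
#' `nu` degrees of freedom, location `mu` and scale `sigma`. Low `nu` gives
#' heavy tails (nu = 1 is the Cauchy); as `nu` grows the distribution
#' approaches the normal.
#'
#' @param y numeric value(s) at which to evaluate.
#' @param nu degrees of freedom, > 0.
#' @param mu location.
#' @param sigma scale, > 0.
#' @return Log density, vectorized over `y`.
#' @export
#' @examples
#' student_t_log_density(0, nu = 1, mu = 0, sigma = 1) # log(1/pi)
student_t_log_density <- function(y, nu, mu, sigma) {
  if (!is.finite(nu) || nu <= 0) stop_domain("'nu' must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop_domain("'sigma' must be > 0")
  .st_lpdf_cpp(as.numeric(y), nu, mu, sigma)
}

#' Bayesian t-test
#'
#' Fits a scaled and shifted Student-t distribution to a vector of
#' measurements, yielding posterior draws for the location `mu`, scale
#' `sigma` and degrees of freedom `nu`. Each group is fitted independently;
#' groups are compared afterwards with [compare_means()]. The `mu` draws are
#' the fit's mean draws for comparison purposes.
#'
#' Default priors are flat on `mu`, `log(sigma)` and `log(nu)` (with `nu`
#' restricted to `[0.1, 1e4]` so the posterior stays proper for normal-like
#' data); custom priors on the natural scale can be supplied through
#' `priors`.
#'
#' @param y numeric vector of at least two finite, non-constant values.
#' @param priors named list of [bprior()] objects or prior strings for
#'   `"mu"`, `"sigma"`, `"nu"`.
#' @param chains,warmup,iter,seed sampler settings, see [sampler_settings()].
#' @return An object of class `c("bpsy_ttest", "bpsy_fit")`.
#' @export
#' @examples
#' fit <- b_ttest(rnorm(50, 5, 2), chains = 2, warmup = 200, iter = 200,
#'                seed = 1)
#' summary(fit)
b_ttest <- function(y, priors = NULL, chains = 4, warmup = 1000, iter = 1000,
                    seed = NULL) {
  if (!is.numeric(y) || length(y) < 2L)
    stop_validation("'y' must be a numeric vector with at least 2 values")
  if (anyNA(y) || any(!is.finite(y)))
    stop_validation("'y' must contain only finite values")
  if (sd(y) == 0)
    stop_degenerate("'y' is constant; the scale posterior is degenerate")
  settings <- sampler_settings(chains, warmup, iter, seed)
  pars <- c("mu", "sigma", "nu")
  priors <- normalize_priors(priors, pars)
  pm <- prior_matrix(priors, pars)

  run_one <- function(chain) {
    init <- c(mean(y) + sd(y) * rnorm(1) * 0.2,
              sd(y) * exp(0.2 * rnorm(1)),
              exp(runif(1, log(2), log(50))))
    .chain_ttest_cpp(y, settings$warmup, settings$iter, init, pm)
  }
  values <- run_chains(settings, run_one, 3L)
  new_bfit("ttest", "bpsy_ttest", values, pars,
           group_pars = pars, subject_pars = character(),
           n_subjects = 0L, data = list(y = y),
           settings = settings, priors = priors)
}
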