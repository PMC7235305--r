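#' Prior distributions
#'
#' Construct a prior for a model parameter. Supported families are
#' `uniform(lo, hi)`, `normal(mean, sd)`, `gamma(shape, rate)`,
#' `beta(alpha, beta)` and the default improper `flat` prior, which
#' contributes zero log density everywhere on the parameter's declared
#' support.
#'
#' @param family one of `"uniform"`, `"normal"`, `"gamma"`, `"beta"`,
#'   `"flat"`.
#' @param params numeric vector of two family-specific parameters (none for
#'   `flat`).
#' @return An object of class `bpsy_prior`.
#' @export
#' @examples
#' bprior("normal", c(0, 1))
#' bprior("flat")
bprior <- function(family = c("flat", "uniform", "normal", "gamma", "beta"),
                   params = numeric()) {
  family <- match.arg(family)
  params <- as.numeric(params)
  if (family == "flat") {
    if (length(params) != 0L)
      stop_validation("flat priors take no parameters")
  } else {
    if (length(params) != 2L || anyNA(params) || any(!is.finite(params)))
      stop_validation(sprintf("%s priors need two finite parameters", family))
    ok <- switch(family,
                 uniform = params[1] < params[2],
                 normal  = params[2] > 0,
                 gamma   = all(params > 0),
                 beta    = all(params > 0))
    if (!ok)
      stop_validation(sprintf("invalid parameters for %s prior: (%g, %g)",
                              family, params[1], params[2]))
  }
  structure(list(family = family, params = params), class = "bpsy_prior")
}

#' @export
print.bpsy_prior <- function(x, ...) {
  if (x$family == "flat") cat("prior: flat\n")
  else cat(sprintf("prior: %s(%g, %g)\n", x$family, x$params[1], x$params[2]))
  invisible(x)
}

#' Log density of a prior at a value
#'
#' Returns the log prior density at `value`; `-Inf` outside the support of a
#' proper prior and 0 everywhere for the improper flat prior (the declared
#' support of the parameter the prior is attached to is enforced by the
#' model, not here).
#'
#' @param prior a [bprior()] object.
#' @param value numeric value(s) at which to evaluate.
#' @return Log density, vectorized over `value`.
#' @export
prior_log_density <- function(prior, value) {
  if (!inherits(prior, "bpsy_prior"))
    stop_validation("'prior' must be a bpsy_prior (see bprior())")
  p <- prior$params
  switch(prior$family,
         flat    = rep(0, length(value)),
         uniform = dunif(value, p[1], p[2], log = TRUE),
         normal  = dnorm(value, p[1], p[2], log = TRUE),
         gamma   = dgamma(value, shape = p[1], rate = p[2], log = TRUE),
         beta    = dbeta(value, p[1], p[2], log = TRUE))
}

#' Parse a prior from its text form
#'
#' Accepts strings like `"normal(0, 1)"`, `"uniform(0, 200)"`, or `"flat"`,
#' the form used in config files and on the command line
#' (`--prior "mu:normal(0,1)"`).
#'
#' @param text a single string.
#' @return A [bprior()] object.
#' @export
parse_prior <- function(text) {
  text <- trimws(text)
  if (tolower(text) == "flat") return(bprior("flat"))
  m <- regmatches(text, regexec("^([a-z]+)\\(([^,]+),([^)]+)\\)$", text))[[1]]
  if (length(m) != 4L)
    stop_validation(sprintf(
      "cannot parse prior '%s'; expected e.g. normal(0,1) or flat", text))
  fam <- m[2]
  if (!fam %in% c("uniform", "normal", "gamma", "beta"))
    stop_validation(sprintf("unknown prior family '%s'", fam))
  vals <- suppressWarnings(as.numeric(c(m[3], m[4])))
  if (anyNA(vals))
    stop_validation(sprintf("non-numeric prior parameters in '%s'", text))
  bprior(fam, vals)
}

# Normalize a user prior map: NULL, bpsy_prior objects or strings, named by
# parameter. Unknown parameter names raise a lookup error listing valid ones.
normalize_priors <- function(priors, par_names) {
  if (is.null(priors)) return(list())
  if (!is.list(priors) || is.null(names(priors)) || any(names(priors) == ""))
    stop_validation("'priors' must be a named list of priors")
  bad <- setdiff(names(priors), par_names)
  if (length(bad))
    stop_lookup(sprintf("no parameter named %s; priors can be set on: %s",
                        paste(sQuote(bad), collapse = ", "),
                        paste(par_names, collapse = ", ")))
  lapply(priors, function(p) {
    if (is.character(p)) parse_prior(p)
    else if (inherits(p, "bpsy_prior")) p
    else stop_validation("each prior must be a bpsy_prior or a string")
  })
}

# 3-column (family code, a, b) matrix for the compiled samplers; rows follow
# par_names, family code 0 marks the default flat prior.
prior_matrix <- function(priors, par_names) {
  codes <- c(flat = 0, uniform = 1, normal = 2, gamma = 3, beta = 4)
  m <- matrix(0, nrow = length(par_names), ncol = 3)
  for (i in seq_along(par_names)) {
    p <- priors[[par_names[i]]]
    if (!is.null(p) && p$family != "flat")
      m[i, ] <- c(codes[[p$family]], p$params[1], p$params[2])
  }
  m
}
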