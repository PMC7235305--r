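# Shared infrastructure for fitted-model objects. Every b_* fitting function
# returns a list of class c("bpsy_<model>", "bpsy_fit") holding one
# draw_matrix with group-level parameters first and subject-level parameters
# (named "par[i]") after them.

new_bfit <- function(model, class1, values, par_names, group_pars,
                     subject_pars, n_subjects, data, settings, priors) {
  structure(list(model = model,
                 draws = draw_matrix(values, par_names),
                 group_pars = group_pars,
                 subject_pars = subject_pars,
                 n_subjects = n_subjects,
                 data = data,
                 settings = settings,
                 priors = priors),
            class = c(class1, "bpsy_fit"))
}

# Run one compiled chain function across all chains; run_one(chain) must draw
# its own (seeded) initial values and return an iter x K matrix. Initial
# values are retried with fresh jitter if the sampler rejects them.
run_chains <- function(settings, run_one, n_par) {
  out <- array(NA_real_, c(settings$chains, settings$iter, n_par))
  for (chain in seq_len(settings$chains)) {
    set.seed(chain_seed(settings, chain))
    res <- NULL
    for (try in 1:100) {
      res <- tryCatch(run_one(chain), error = function(e) e)
      if (!inherits(res, "error")) break
      if (!grepl("non-finite log posterior", conditionMessage(res))) stop(res)
    }
    if (inherits(res, "error"))
      bpsy_stop("could not find finite initial log density in 100 tries",
                "bpsy_init_error")
    out[chain, , ] <- res
  }
  out
}

validate_subjects <- function(s, what = "s") {
  if (anyNA(s) || any(!is.finite(s)) || any(s != round(s)))
    stop_validation(sprintf("'%s' must contain integer subject indexes", what))
  s <- as.integer(s)
  n <- max(s)
  if (min(s) != 1L || !all(seq_len(n) %in% s))
    stop_validation(paste0(
      "subject indexes must be contiguous integers from 1 to n; ",
      "re-index your subjects to the interval [1, n] ",
      "(e.g. s <- as.integer(factor(s)))"))
  s
}

#' @export
print.bpsy_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s model fit\n", x$model))
  cat(sprintf("  chains: %d, warmup: %d, iterations: %d, seed: %d\n",
              x$settings$chains, x$settings$warmup, x$settings$iter,
              x$settings$seed))
  if (length(x$subject_pars))
    cat(sprintf("  subjects: %d\n", x$n_subjects))
  rep <- summarize_fit(x)
  cat("\n")
  print(format(rep, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
summary.bpsy_fit <- function(object, ...) {
  rep <- summarize_fit(object)
  rep[rep$parameter %in% object$group_pars, , drop = FALSE]
}

#' @export
coef.bpsy_fit <- function(object, ...) {
  vapply(object$group_pars,
         function(p) mean(flatten_param(object$draws, p)), 0)
}

#' Extract group-level posterior draws
#'
#' Returns the flattened post-warmup draws of one group-level parameter in
#' chain-major order (all draws of chain 1 first), with length
#' `chains * iter`.
#'
#' @param fit a fitted model object.
#' @param parameter group-level parameter name.
#' @return Numeric vector of draws.
#' @export
extract_group_draws <- function(fit, parameter) {
  if (!inherits(fit, "bpsy_fit")) stop_validation("'fit' must be a bpsy fit")
  if (!parameter %in% fit$group_pars)
    stop_lookup(sprintf(
      "no group-level parameter '%s'; available: %s", parameter,
      paste(fit$group_pars, collapse = ", ")))
  flatten_param(fit$draws, parameter)
}

#' Extract subject-level posterior draws
#'
#' @param fit a hierarchical fitted model object.
#' @param parameter subject-level parameter name (e.g. `"mu"`).
#' @param subject subject index in `1..n_subjects`.
#' @return Numeric vector of draws for that subject's parameter.
#' @export
extract_subject_draws <- function(fit, parameter, subject) {
  if (!inherits(fit, "bpsy_fit")) stop_validation("'fit' must be a bpsy fit")
  if (!length(fit$subject_pars))
    stop_unsupported(sprintf(
      "the %s model has no subject-level parameters", fit$model))
  if (!parameter %in% fit$subject_pars)
    stop_lookup(sprintf(
      "no subject-level parameter '%s'; available: %s", parameter,
      paste(fit$subject_pars, collapse = ", ")))
  subject <- as.integer(subject)
  if (is.na(subject) || subject < 1L || subject > fit$n_subjects)
    stop_index(sprintf("subject must be in 1..%d", fit$n_subjects))
  flatten_param(fit$draws, sprintf("%s[%d]", parameter, subject))
}

#' Group-level parameters as a data frame
#'
#' One column per group-level parameter, one row per posterior draw
#' (chain-major order).
#'
#' @param fit a fitted model object.
#' @return A `data.frame` of posterior draws.
#' @export
get_parameters <- function(fit) {
  if (!inherits(fit, "bpsy_fit")) stop_validation("'fit' must be a bpsy fit")
  as.data.frame(lapply(setNames(fit$group_pars, fit$group_pars),
                       function(p) flatten_param(fit$draws, p)))
}

#' Subject-level parameters as a data frame
#'
#' Long format: one column per subject-level parameter plus a `subject`
#' column; rows are posterior draws stacked by subject.
#'
#' @param fit a hierarchical fitted model object.
#' @return A `data.frame` of subject-level posterior draws.
#' @export
get_subject_parameters <- function(fit) {
  if (!inherits(fit, "bpsy_fit")) stop_validation("'fit' must be a bpsy fit")
  if (!length(fit$subject_pars))
    stop_unsupported(sprintf(
      "the %s model has no subject-level parameters", fit$model))
  blocks <- lapply(seq_len(fit$n_subjects), function(i) {
    cols <- lapply(setNames(fit$subject_pars, fit$subject_pars),
                   function(p) flatten_param(fit$draws,
                                             sprintf("%s[%d]", p, i)))
    cbind(data.frame(subject = i), as.data.frame(cols))
  })
  do.call(rbind, blocks)
}

# draws CSV layout shared by the fitting functions and the CLI: a comment
# line tagging the model, then chain, iteration and one column per parameter
write_fit_csv <- function(fit, path) {
  dm <- fit$draws
  d <- dim(dm$values)
  flat <- do.call(cbind, lapply(dm$parameter_names,
                                function(p) flatten_param(dm, p)))
  colnames(flat) <- dm$parameter_names
  df <- cbind(data.frame(chain = rep(seq_len(d[1]), each = d[2]),
                         iteration = rep(seq_len(d[2]), d[1])),
              as.data.frame(flat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bpsy fit model=%s n_subjects=%d",
                     fit$model, fit$n_subjects), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_fit_csv <- function(path) {
  header <- readLines(path, n = 1L)
  model <- sub(".*model=([a-z_]+).*", "\\1", header)
  n_subjects <- as.integer(sub(".*n_subjects=([0-9]+).*", "\\1", header))
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  chains <- max(df$chain)
  iter <- max(df$iteration)
  pars <- setdiff(names(df), c("chain", "iteration"))
  values <- array(NA_real_, c(chains, iter, length(pars)))
  for (j in seq_along(pars))
    for (ch in seq_len(chains))
      values[ch, , j] <- df[df$chain == ch, pars[j]]
  list(model = model, n_subjects = n_subjects,
       draws = draw_matrix(values, pars))
}
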