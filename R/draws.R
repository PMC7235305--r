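#' Posterior draw container
#'
#' A `draw_matrix` stores posterior draws as a 3-dimensional array indexed by
#' (chain, iteration, parameter). It is the common currency passed between the
#' samplers, the convergence diagnostics and the comparison framework. Draws
#' are post-warmup: warmup iterations are discarded by the samplers before a
#' `draw_matrix` is built.
#'
#' @param values numeric array with dimensions (chains, iterations,
#'   parameters), or a (iterations x parameters) matrix for a single chain.
#' @param parameter_names character vector naming the parameter axis; unique
#'   and of matching length.
#' @param warmup_discarded logical flag recording that warmup has been
#'   removed (always `TRUE` for draws produced by this package).
#'
#' @return An object of class `draw_matrix`.
#' @export
#' @examples
#' dm <- draw_matrix(array(rnorm(2 * 100 * 1), c(2, 100, 1)), "mu")
#' dim(dm)
draw_matrix <- function(values, parameter_names = NULL, warmup_discarded = TRUE) {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_validation("'values' must be a (chain, iteration, parameter) array")
  if (dim(values)[2] < 1L)
    stop_validation("at least one iteration per chain is required")
  if (is.null(parameter_names))
    parameter_names <- dimnames(values)[[3]]
  if (is.null(parameter_names))
    parameter_names <- paste0("par", seq_len(dim(values)[3]))
  if (length(parameter_names) != dim(values)[3])
    stop_validation("'parameter_names' length must match the parameter axis")
  if (anyDuplicated(parameter_names))
    stop_validation("'parameter_names' must be unique")
  dimnames(values) <- list(NULL, NULL, parameter_names)
  structure(list(values = values,
                 parameter_names = parameter_names,
                 warmup_discarded = isTRUE(warmup_discarded)),
            class = "draw_matrix")
}

#' @export
dim.draw_matrix <- function(x) dim(x$values)

#' @export
print.draw_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("draw_matrix: %d chain(s) x %d iteration(s) x %d parameter(s)\n",
              d[1], d[2], d[3]))
  cat("parameters:", paste(x$parameter_names, collapse = ", "), "\n")
  invisible(x)
}

# chain-major flattening of one parameter: all draws of chain 1, then chain 2, ...
flatten_param <- function(dm, parameter) {
  i <- match(parameter, dm$parameter_names)
  if (is.na(i))
    stop_lookup(sprintf("unknown parameter '%s'; available: %s", parameter,
                        paste(dm$parameter_names, collapse = ", ")))
  as.vector(t(dm$values[, , i, drop = TRUE]))
}

# (chains x iterations) matrix for one parameter
param_chains <- function(dm, parameter) {
  i <- match(parameter, dm$parameter_names)
  if (is.na(i))
    stop_lookup(sprintf("unknown parameter '%s'; available: %s", parameter,
                        paste(dm$parameter_names, collapse = ", ")))
  matrix(dm$values[, , i], nrow = dim(dm$values)[1])
}

#' Highest density interval of a set of draws
#'
#' The HDI is the shortest interval containing a given posterior mass. It is
#' computed by the sorted-window convention: among all contiguous windows of
#' `ceiling(mass * n)` sorted draws the shortest one is returned, ties broken
#' in favour of the smallest lower bound.
#'
#' @param draws numeric vector of at least two draws.
#' @param mass probability mass of the interval, strictly between 0 and 1.
#' @return A list of class `bpsy_hdi` with elements `lower`, `upper`, `mass`.
#' @export
#' @examples
#' compute_hdi(rnorm(1e4), 0.95)
compute_hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(draws) || length(draws) < 2L)
    stop_validation("'draws' must be a numeric vector with at least 2 values")
  if (anyNA(draws) || any(!is.finite(draws)))
    stop_validation("'draws' must be finite")
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop_validation("'mass' must be a single probability in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  k <- n - m + 1L                      # number of candidate windows
  widths <- x[m:n] - x[1:k]
  i <- which.min(widths)               # first minimum = smallest lower bound
  structure(list(lower = x[i], upper = x[i + m - 1L], mass = mass),
            class = "bpsy_hdi")
}

#' @export
print.bpsy_hdi <- function(x, ...) {
  cat(sprintf("%.0f%% HDI: [%g, %g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Split potential scale reduction factor
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed on the split chains: `sqrt(var_plus / W)` where
#' `var_plus = ((n - 1) W + B) / n`, `W` the mean within-chain variance and
#' `B` the between-chain variance of the half-chain means. Values near 1
#' indicate that the chains agree; the statistic is invariant under affine
#' transformations of the draws.
#'
#' @param draws a [draw_matrix].
#' @param parameter name of the parameter to diagnose.
#' @return The split R-hat value.
#' @export
split_rhat <- function(draws, parameter) {
  ch <- param_chains(draws, parameter)
  n <- ncol(ch)
  if (n < 2L)
    stop_validation("at least 2 iterations per chain are required")
  h <- n %/% 2L
  halves <- rbind(ch[, 1:h, drop = FALSE],
                  ch[, (n - h + 1L):n, drop = FALSE])
  w_j <- apply(halves, 1, var)
  W <- mean(w_j)
  if (!is.finite(W) || W <= 0)
    stop_degenerate("zero within-chain variance: chains are (half-)constant")
  mns <- rowMeans(halves)
  B <- h * var(mns)
  var_plus <- ((h - 1) * W + B) / h
  sqrt(var_plus / W)
}

#' Effective sample size
#'
#' Autocorrelation-based effective sample size: per-chain autocorrelations
#' are averaged across chains and summed under Geyer's initial positive
#' sequence rule (summation stops before the first negative paired sum).
#' The estimate is capped at the total number of draws, so independent draws
#' report approximately (and never more than) the nominal draw count.
#'
#' @inheritParams split_rhat
#' @return The effective sample size estimate.
#' @export
effective_sample_size <- function(draws, parameter) {
  ch <- param_chains(draws, parameter)
  n <- ncol(ch)
  n_chain <- nrow(ch)
  if (n < 2L)
    stop_validation("at least 2 iterations per chain are required")
  if (all(apply(ch, 1, var) <= 0) || !is.finite(sum(apply(ch, 1, var))))
    stop_degenerate("zero within-chain variance: cannot estimate n_eff")
  lag_max <- min(n - 1L, 2000L)
  rho <- rep(0, lag_max + 1L)
  used <- 0L
  for (j in seq_len(n_chain)) {
    v <- var(ch[j, ])
    if (v <= 0) next
    a <- acf(ch[j, ], lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    rho <- rho + a
    used <- used + 1L
  }
  rho <- rho / used
  # Geyer initial positive sequence on paired sums rho[2k] + rho[2k+1]
  tau <- -1
  k <- 1L
  while (k <= lag_max) {
    g <- rho[k] + if (k + 1L <= lag_max + 1L) rho[k + 1L] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
    k <- k + 2L
  }
  total <- n * n_chain
  ess <- total / max(tau, .Machine$double.eps)
  min(ess, total)
}

#' Convergence and summary report for a fitted model
#'
#' One row per parameter (group level first, then subject level for
#' hierarchical fits) with the posterior mean, Monte Carlo standard error
#' (`se_mean = sd / sqrt(n_eff)`), posterior sd, central 2.5% and 97.5%
#' quantiles, effective sample size and split R-hat.
#'
#' @param fit a fitted model object (see [b_ttest()] and friends) or a
#'   [draw_matrix].
#' @return A `data.frame` with columns `parameter`, `mean`, `se_mean`, `sd`,
#'   `q2.5`, `q97.5`, `n_eff`, `rhat`.
#' @export
summarize_fit <- function(fit) {
  dm <- if (inherits(fit, "draw_matrix")) fit
        else if (inherits(fit, "bpsy_fit")) fit$draws
        else stop_validation("'fit' must be a bpsy fit or a draw_matrix")
  pars <- dm$parameter_names
  if (length(pars) < 1L) stop_validation("fit contains no parameters")
  rows <- lapply(pars, function(p) {
    x <- flatten_param(dm, p)
    n_eff <- effective_sample_size(dm, p)
    s <- sd(x)
    data.frame(parameter = p,
               mean = mean(x),
               se_mean = s / sqrt(n_eff),
               sd = s,
               q2.5 = unname(quantile(x, 0.025)),
               q97.5 = unname(quantile(x, 0.975)),
               n_eff = n_eff,
               rhat = split_rhat(dm, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a summary report as delimited text
#'
#' Serializes the output of [summarize_fit()] with the conventional column
#' header (`parameter, mean, se_mean, sd, 2.5%, 97.5%, n_eff, Rhat`).
#'
#' @param report data.frame from [summarize_fit()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(report, path) {
  out <- report
  names(out) <- c("parameter", "mean", "se_mean", "sd", "2.5%", "97.5%",
                  "n_eff", "Rhat")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
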