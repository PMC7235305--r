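#' Bayesian bootstrap
#'
#' Simulates the posterior distribution of a statistic by drawing
#' observation weights from a uniform Dirichlet distribution of the same
#' dimension as the number of data points (Rubin's scheme). In the default
#' weighted mode each draw of weights is handed to the statistic together
#' with the data; in resampling mode the data are resampled (n rows, with
#' probabilities equal to the weights) and the statistic receives the
#' resample with uniform weights.
#'
#' @param data numeric vector, matrix or data.frame (rows are observations).
#' @param statistic function `(data, weights)` returning a numeric scalar or
#'   vector; a one-argument function is allowed in resampling mode.
#' @param n_draws number of posterior draws.
#' @param seed integer seed; drawn and recorded if `NULL`.
#' @param use_weights `TRUE` for the weighted mode, `FALSE` for resampling;
#'   defaults to weighted whenever the statistic accepts a weights argument.
#' @return An object of class `c("bpsy_bootstrap", "bpsy_fit")`; the
#'   statistic draws are in `$draws` (a vector, or a matrix with one row per
#'   draw for vector-valued statistics).
#' @export
#' @examples
#' b <- b_bootstrap(c(1, 2, 3), weighted_mean, n_draws = 1000, seed = 1)
#' mean(b$draws)
b_bootstrap <- function(data, statistic, n_draws = 4000, seed = NULL,
                        use_weights = NULL) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 1L) stop_validation("'data' must contain at least one observation")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L)
    stop_validation("'n_draws' must be a positive integer")
  if (!is.function(statistic)) stop_validation("'statistic' must be a function")
  takes_weights <- length(formals(statistic)) >= 2L
  if (is.null(use_weights)) use_weights <- takes_weights
  if (use_weights && !takes_weights)
    stop_validation("'statistic' must accept (data, weights) in weighted mode")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  set.seed(seed)

  take_rows <- function(d, idx) if (is.null(dim(d))) d[idx] else d[idx, , drop = FALSE]
  out <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    # uniform Dirichlet via normalized unit exponentials
    e <- rexp(n)
    w <- e / sum(e)
    val <- if (use_weights) {
      statistic(data, w)
    } else {
      res <- take_rows(data, sample.int(n, n, replace = TRUE, prob = w))
      if (takes_weights) statistic(res, rep(1 / n, n)) else statistic(res)
    }
    if (anyNA(val) || any(!is.finite(val)))
      stop_validation(sprintf("statistic returned a non-finite value at draw %d", i))
    out[[i]] <- val
  }
  draws <- if (length(out[[1]]) == 1L) unlist(out) else do.call(rbind, out)
  structure(list(model = "bootstrap", draws = draws, n_draws = n_draws,
                 seed = seed, use_weights = use_weights),
            class = c("bpsy_bootstrap", "bpsy_fit"))
}

#' @export
print.bpsy_bootstrap <- function(x, ...) {
  cat(sprintf("Bayesian bootstrap: %d draws (%s mode), seed %d\n",
              x$n_draws, if (x$use_weights) "weighted" else "resampling",
              x$seed))
  d <- if (is.matrix(x$draws)) x$draws[, 1] else x$draws
  h <- compute_hdi(d, 0.95)
  cat(sprintf("  mean %g, sd %g, 95%% HDI [%g, %g]\n",
              mean(d), sd(d), h$lower, h$upper))
  invisible(x)
}

#' Built-in weighted statistics
#'
#' Weighted statistics with the `(data, weights)` contract used by
#' [b_bootstrap()]: `weighted_mean`, `weighted_sd` (square root of the
#' weighted variance around the weighted mean), `weighted_median` and
#' `weighted_quantile(q)` (weighted CDF inversion).
#'
#' @param x numeric vector.
#' @param w weights summing to 1.
#' @param q quantile level for `weighted_quantile`.
#' @return The weighted statistic (for `weighted_quantile`, a `(data,
#'   weights)` statistic function).
#' @export
weighted_mean <- function(x, w) sum(x * w)

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  m <- sum(x * w)
  sqrt(sum(w * (x - m)^2))
}

#' @rdname weighted_mean
#' @export
weighted_median <- function(x, w) weighted_quantile(0.5)(x, w)

#' @rdname weighted_mean
#' @export
weighted_quantile <- function(q) {
  force(q)
  function(x, w) {
    o <- order(x)
    cw <- cumsum(w[o])
    x[o][which(cw >= q)[1]]
  }
}
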