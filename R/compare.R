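#' Mean-parameter draws of a fit
#'
#' Every model designates one vector of posterior draws as "the mean" for
#' comparison purposes: `mu` for the t-test, `mu_mu + 1/mu_lambda` for the
#' reaction-time model, the group `p` for the success-rate model, `mu_a` /
#' `mu_b` / `mu_s` for the linear model (selected with `par = "intercept"`,
#' `"slope"` or `"sigma"`), the per-component location for the color model
#' (`par` one of `"r", "g", "b", "s", "v", "h"`; hue draws are circular) and
#' the statistic draws for a bootstrap. Plain numeric vectors pass through
#' unchanged.
#'
#' @param fit a fitted model object, bootstrap, or numeric vector.
#' @param par optional parameter selector (required for linear and color
#'   fits).
#' @return Numeric vector of draws; hue draws carry `attr(, "circular") =
#'   TRUE` and are in radians.
#' @export
mean_draws_of <- function(fit, par = NULL) {
  if (is.numeric(fit)) return(as.numeric(fit))
  if (inherits(fit, "bpsy_bootstrap")) {
    if (is.matrix(fit$draws))
      stop_selector("vector-valued bootstrap: select a column yourself")
    return(fit$draws)
  }
  if (inherits(fit, "bpsy_ttest")) return(extract_group_draws(fit, "mu"))
  if (inherits(fit, "bpsy_reaction_time")) return(rt_group_mean_draws(fit))
  if (inherits(fit, "bpsy_success_rate")) return(extract_group_draws(fit, "p"))
  if (inherits(fit, "bpsy_linear")) {
    if (is.null(par))
      stop_selector(paste0("linear fits need par = \"intercept\", \"slope\" ",
                           "or \"sigma\""))
    p <- switch(match.arg(par, c("intercept", "slope", "sigma")),
                intercept = "mu_a", slope = "mu_b", sigma = "mu_s")
    return(extract_group_draws(fit, p))
  }
  if (inherits(fit, "bpsy_color")) {
    if (is.null(par))
      stop_selector("color fits need par, one of: r, g, b, s, v, h")
    par <- match.arg(par, c("r", "g", "b", "s", "v", "h"))
    if (par == "h") {
      # hue is reported in degrees at the interface; differences (and any
      # ROPE) are wrapped on the 360-degree circle
      d <- extract_group_draws(fit, "mu_h") * 180 / pi
      attr(d, "circular") <- TRUE
      attr(d, "period") <- 360
      return(d)
    }
    return(extract_group_draws(fit, paste0("mu_", par)))
  }
  stop_validation("unsupported object for mean_draws_of()")
}

# probabilities and HDI for one difference vector; ties without a ROPE are
# split evenly between the two sides
pair_core <- function(d, rope, hdi_mass = 0.95) {
  n <- length(d)
  if (is.null(rope)) {
    ties <- sum(d == 0)
    p_gt <- (sum(d > 0) + 0.5 * ties) / n
    p_lt <- (sum(d < 0) + 0.5 * ties) / n
    p_eq <- NA_real_
  } else {
    p_eq <- sum(d >= rope[1] & d <= rope[2]) / n
    p_gt <- sum(d > rope[2]) / n
    p_lt <- sum(d < rope[1]) / n
  }
  h <- if (n >= 2L) compute_hdi(d, hdi_mass)
       else list(lower = d, upper = d)
  # reported +/- on the probability: sd of per-segment probabilities over
  # contiguous segments of the draw sequence
  nseg <- min(10L, n)
  se <- NA_real_
  if (nseg >= 2L) {
    seg <- cut(seq_len(n), nseg, labels = FALSE)
    pseg <- tapply(if (is.null(rope)) d > 0 else d > rope[2], seg, mean)
    se <- sd(pseg) / sqrt(nseg)
  }
  list(p_lt = p_lt, p_gt = p_gt, p_eq = p_eq,
       hdi_lower = h$lower, hdi_upper = h$upper, se_prob = se, n = n)
}

check_rope <- function(rope) {
  if (is.null(rope)) return(NULL)
  rope <- as.numeric(rope)
  if (length(rope) != 2L || anyNA(rope) || rope[1] >= rope[2])
    stop_validation("'rope' must be c(lower, upper) with lower < upper")
  rope
}

#' Pairwise comparison of two draw vectors
#'
#' Draw-aligned comparison: the difference `d_i = a_i - b_i` is formed per
#' draw index, and probabilities are proportions of those differences.
#' Without a ROPE, `P(a > b)` counts positive differences (exact ties split
#' evenly); with a ROPE `[lower, upper]`, differences inside it count as
#' "practically equal" and the strict probabilities are computed on the
#' remaining draws. The 95% HDI of the difference is always reported.
#'
#' @param a,b numeric draw vectors of equal length (>= 2).
#' @param rope optional `c(lower, upper)` region of practical equivalence.
#' @param circular treat `a` and `b` as angles in radians and wrap the
#'   difference into `(-pi, pi]` (set automatically for hue draws).
#' @return An object of class `bpsy_comparison`.
#' @export
#' @examples
#' compare_means_pair(c(123, 128, 121, 137, 110),
#'                    c(118, 126, 119, 110, 122)) # P(a > b) = 0.8
compare_means_pair <- function(a, b, rope = NULL, circular = FALSE) {
  if (length(a) != length(b))
    stop_alignment(paste0("draw vectors differ in length (", length(a), " vs ",
                          length(b), "); refit with identical chains x iter"))
  if (length(a) < 2L)
    stop_validation("at least 2 draws are required")
  rope <- check_rope(rope)
  circular <- isTRUE(circular) || isTRUE(attr(a, "circular")) ||
    isTRUE(attr(b, "circular"))
  period <- attr(a, "period")
  if (is.null(period)) period <- attr(b, "period")
  if (is.null(period)) period <- 2 * pi
  d <- if (circular) wrap_angle_diff(as.numeric(a) - as.numeric(b), period)
       else as.numeric(a) - as.numeric(b)
  res <- pair_core(d, rope)
  pairs <- data.frame(group_a = 1L, group_b = 2L,
                      p_smaller = res$p_lt, p_greater = res$p_gt,
                      p_equal = res$p_eq,
                      hdi_lower = res$hdi_lower, hdi_upper = res$hdi_upper,
                      se_prob = res$se_prob)
  structure(list(pairs = pairs, extremes = NULL, n_groups = 2L,
                 rope = rope, n_draws = length(a)),
            class = "bpsy_comparison")
}

#' Multi-group comparison of draw vectors
#'
#' All ordered pairs are compared as in [compare_means_pair()]; in addition
#' each group's probability of having the largest (and the smallest) mean is
#' estimated as the fraction of draw indexes at which that group's draw is
#' the maximum (minimum), ties split evenly among the tied groups.
#'
#' @param draw_sets list of two or more equal-length numeric draw vectors.
#' @param rope optional `c(lower, upper)` region of practical equivalence.
#' @param circular wrap differences as angles, see [compare_means_pair()].
#' @return An object of class `bpsy_comparison` with a `$pairs` data.frame
#'   and, for more than two groups, an `$extremes` data.frame with columns
#'   `group`, `p_largest`, `p_smallest`.
#' @export
compare_means_multi <- function(draw_sets, rope = NULL, circular = FALSE) {
  k <- length(draw_sets)
  if (k < 2L) stop_validation("at least 2 draw sets are required")
  n <- unique(vapply(draw_sets, length, 0L))
  if (length(n) != 1L)
    stop_alignment("all draw sets must have the same length; equalize chains x iter")
  rope <- check_rope(rope)
  circular <- isTRUE(circular) ||
    any(vapply(draw_sets, function(x) isTRUE(attr(x, "circular")), TRUE))
  periods <- unlist(lapply(draw_sets, attr, "period"))
  period <- if (length(periods)) periods[1] else 2 * pi

  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- as.numeric(draw_sets[[i]]) - as.numeric(draw_sets[[j]])
    if (circular) d <- wrap_angle_diff(d, period)
    res <- pair_core(d, rope)
    rows[[length(rows) + 1L]] <-
      data.frame(group_a = i, group_b = j,
                 p_smaller = res$p_lt, p_greater = res$p_gt,
                 p_equal = res$p_eq, hdi_lower = res$hdi_lower,
                 hdi_upper = res$hdi_upper, se_prob = res$se_prob)
  }
  extremes <- NULL
  if (k > 2L) {
    M <- do.call(rbind, draw_sets)            # k x n
    mx <- do.call(pmax, draw_sets)
    mn <- do.call(pmin, draw_sets)
    is_max <- sweep(M, 2, mx, "==")
    is_min <- sweep(M, 2, mn, "==")
    p_largest <- rowMeans(sweep(is_max, 2, colSums(is_max), "/"))
    p_smallest <- rowMeans(sweep(is_min, 2, colSums(is_min), "/"))
    extremes <- data.frame(group = seq_len(k),
                           p_largest = p_largest, p_smallest = p_smallest)
  }
  structure(list(pairs = do.call(rbind, rows), extremes = extremes,
                 n_groups = k, rope = rope, n_draws = n),
            class = "bpsy_comparison")
}

#' Compare draws to a fixed reference point
#'
#' Equivalent to [compare_means_pair()] against a constant vector at
#' `point`, e.g. to ask whether a mean differs from 0.
#'
#' @param a numeric draw vector.
#' @param point the reference value.
#' @param rope optional region of practical equivalence.
#' @param circular wrap differences as angles.
#' @return An object of class `bpsy_comparison`.
#' @export
compare_mean_to_point <- function(a, point, rope = NULL, circular = FALSE) {
  if (!length(a)) stop_validation("'a' must be non-empty")
  compare_means_pair(a, rep(point, length(a)), rope = rope,
                     circular = circular)
}

#' Compare the means of fitted models
#'
#' The fit-level front end of the comparison framework: extracts each fit's
#' mean-parameter draws ([mean_draws_of()]) and runs the draw-aligned
#' pairwise ([compare_means_pair()]) or multi-group
#' ([compare_means_multi()]) comparison. With a single fit and `point`, the
#' mean is compared against the fixed reference value.
#'
#' @param ... two or more fitted models (or numeric draw vectors), or a
#'   single fit together with `point`.
#' @param rope optional `c(lower, upper)` region of practical equivalence.
#' @param par parameter selector for linear (`"intercept"`, `"slope"`,
#'   `"sigma"`) and color (`"r", "g", "b", "s", "v", "h"`) fits.
#' @param point optional reference value for a one-fit comparison.
#' @return An object of class `bpsy_comparison` (printed as a table of
#'   probabilities and HDIs).
#' @export
compare_means <- function(..., rope = NULL, par = NULL, point = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "bpsy_fit"))
    fits <- fits[[1]]
  sets <- lapply(fits, mean_draws_of, par = par)
  if (length(sets) == 1L) {
    if (is.null(point))
      stop_validation("a single fit needs a 'point' to compare against")
    return(compare_mean_to_point(sets[[1]], point, rope = rope))
  }
  if (length(sets) == 2L)
    compare_means_pair(sets[[1]], sets[[2]], rope = rope)
  else
    compare_means_multi(sets, rope = rope)
}

#' @export
print.bpsy_comparison <- function(x, ...) {
  cat(sprintf("Comparison of %d group(s) on %d aligned draws\n",
              x$n_groups, x$n_draws))
  if (!is.null(x$rope))
    cat(sprintf("ROPE: [%g, %g]\n", x$rope[1], x$rope[2]))
  for (r in seq_len(nrow(x$pairs))) {
    p <- x$pairs[r, ]
    cat(sprintf("\nGroup %d vs Group %d:\n", p$group_a, p$group_b))
    cat(sprintf("  P(Group %d < Group %d) = %.4f\n",
                p$group_a, p$group_b, p$p_smaller))
    cat(sprintf("  P(Group %d > Group %d) = %.4f", p$group_a, p$group_b,
                p$p_greater))
    if (!is.na(p$se_prob)) cat(sprintf("  (+/- %.4f)", p$se_prob))
    cat("\n")
    if (!is.na(p$p_equal))
      cat(sprintf("  P(equal within ROPE)  = %.4f\n", p$p_equal))
    cat(sprintf("  95%% HDI of difference: [%g, %g]\n",
                p$hdi_lower, p$hdi_upper))
  }
  if (!is.null(x$extremes)) {
    cat("\nPer-group extremes:\n")
    print(format(x$extremes, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.bpsy_comparison <- function(x, ...) {
  df <- x$pairs
  if (!is.null(x$extremes)) {
    extra <- data.frame(group_a = x$extremes$group, group_b = NA_integer_,
                        p_smaller = x$extremes$p_smallest,
                        p_greater = x$extremes$p_largest,
                        p_equal = NA_real_, hdi_lower = NA_real_,
                        hdi_upper = NA_real_, se_prob = NA_real_)
    df <- rbind(df, extra)
  }
  df
}

# von Mises sampler (Best & Fisher rejection scheme), vectorized over
# mu/kappa so the posterior predictive can use one kappa per draw
rvonmises <- function(n, mu, kappa) {
  mu <- rep_len(mu, n); kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-8
  out[unif] <- runif(sum(unif), 0, 2 * pi)
  todo <- which(!unif)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  while (length(todo)) {
    m <- length(todo)
    z <- cos(pi * runif(m))
    f <- (1 + r[todo] * z) / (r[todo] + z)
    cc <- kappa[todo] * (r[todo] - f)
    u2 <- runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(runif(m) - 0.5) * acos(pmin(pmax(f, -1), 1))
    hit <- todo[ok]
    out[hit] <- (th[ok] + mu[hit]) %% (2 * pi)
    todo <- todo[!ok]
  }
  out
}

# inverse-CDF sampler for the truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Posterior predictive draws from a fitted model
#'
#' For each posterior draw, simulates `n_per_draw` new observations from the
#' model's data distribution at that draw's group-level parameter values
#' (Student-t for the t-test; exGaussian at `(mu_mu, mu_sigma, mu_lambda)`
#' for reaction times; Bernoulli at the group `p` for success rates; normal
#' predictive at a supplied `x` for the linear model; the selected component
#' distribution for the color model) and concatenates the results.
#'
#' @param fit a fitted model object.
#' @param n_per_draw observations simulated per posterior draw.
#' @param seed integer seed; drawn and recorded if `NULL`.
#' @param x value of the independent variable (required for linear fits).
#' @param component color component selector (`"r", "g", "b", "s", "v",
#'   "h"`; required for color fits).
#' @return Numeric vector of length `n_draws * n_per_draw`.
#' @export
posterior_predictive_draws <- function(fit, n_per_draw = 1, seed = NULL,
                                       x = NULL, component = NULL) {
  if (!inherits(fit, "bpsy_fit"))
    stop_validation("'fit' must be a bpsy fit")
  n_per_draw <- as.integer(n_per_draw)
  if (is.na(n_per_draw) || n_per_draw < 1L)
    stop_validation("'n_per_draw' must be a positive integer")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(as.integer(seed))
  rep_par <- function(p) rep(extract_group_draws(fit, p), each = n_per_draw)

  if (inherits(fit, "bpsy_ttest")) {
    mu <- rep_par("mu"); sigma <- rep_par("sigma"); nu <- rep_par("nu")
    return(mu + sigma * rt(length(mu), df = nu))
  }
  if (inherits(fit, "bpsy_reaction_time")) {
    mu <- rep_par("mu_mu"); sg <- rep_par("mu_sigma"); lm <- rep_par("mu_lambda")
    return(rnorm(length(mu), mu, sg) + rexp(length(mu), rate = lm))
  }
  if (inherits(fit, "bpsy_success_rate")) {
    p <- rep_par("p")
    return(rbinom(length(p), 1L, p))
  }
  if (inherits(fit, "bpsy_linear")) {
    if (is.null(x))
      stop_selector("linear predictive draws need a value of 'x'")
    a <- rep_par("mu_a"); b <- rep_par("mu_b"); sg <- rep_par("mu_s")
    return(rnorm(length(a), a + b * x, sg))
  }
  if (inherits(fit, "bpsy_color")) {
    if (is.null(component))
      stop_selector("color predictive draws need a 'component' (r,g,b,s,v,h)")
    component <- match.arg(component, c("r", "g", "b", "s", "v", "h"))
    if (component == "h") {
      mu <- rep_par("mu_h"); kp <- rep_par("kappa_h")
      out <- rvonmises(length(mu), mu, kp)
      attr(out, "circular") <- TRUE
      return(out)
    }
    m <- rep_par(paste0("mu_", component))
    sg <- rep_par(paste0("sigma_", component))
    hi <- if (component %in% c("r", "g", "b")) 255 else 1
    return(rtruncnorm(length(m), m, sg, 0, hi))
  }
  stop_unsupported(sprintf("no posterior predictive for model '%s'", fit$model))
}

#' @export
simulate.bpsy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  posterior_predictive_draws(object, n_per_draw = nsim, seed = seed, ...)
}

#' Compare entire posterior predictive distributions
#'
#' Instead of comparing mean parameters, compares the data distributions
#' implied by the fits: large posterior predictive samples are drawn from
#' each fit ([posterior_predictive_draws()]) and compared draw-aligned with
#' the same ROPE/HDI semantics as [compare_means()]. Fits must be of the
#' same model type.
#'
#' @param ... two or more fitted models of the same type, or a list of them.
#' @param rope optional region of practical equivalence.
#' @param n_per_draw predictive observations per posterior draw.
#' @param seed integer seed.
#' @param x independent-variable value for linear fits.
#' @param component color component for color fits.
#' @return An object of class `bpsy_comparison`.
#' @export
compare_distributions <- function(..., rope = NULL, n_per_draw = 1,
                                  seed = NULL, x = NULL, component = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "bpsy_fit"))
    fits <- fits[[1]]
  if (length(fits) < 2L)
    stop_validation("at least 2 fits are required")
  cls <- vapply(fits, function(f) class(f)[1], "")
  if (length(unique(cls)) != 1L)
    stop_compat(sprintf("cannot compare distributions across model types: %s",
                        paste(unique(cls), collapse = ", ")))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  sets <- lapply(seq_along(fits), function(i)
    posterior_predictive_draws(fits[[i]], n_per_draw = n_per_draw,
                               seed = as.integer(seed) + i, x = x,
                               component = component))
  if (length(sets) == 2L)
    compare_means_pair(sets[[1]], sets[[2]], rope = rope)
  else
    compare_means_multi(sets, rope = rope)
}
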