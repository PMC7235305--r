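# Shared helpers: independent oracles and reduced sampler settings used
# throughout the suite. The oracles deliberately re-derive quantities with
# naive loops so they stay independent of the package's implementation.

quick <- list(chains = 2L, warmup = 400L, iter = 400L)

fit_quick <- function(fun, ..., seed) {
  fun(..., chains = quick$chains, warmup = quick$warmup, iter = quick$iter,
      seed = seed)
}

# exhaustive shortest-window scan over sorted draws
hdi_oracle <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best_w <- Inf
  best <- c(NA, NA)
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best_w) {
      best_w <- w
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

# naive per-index enumeration of the pairwise comparison probabilities
pair_oracle <- function(a, b, rope = NULL) {
  n <- length(a)
  lt <- gt <- eq <- 0
  for (i in seq_len(n)) {
    d <- a[i] - b[i]
    if (is.null(rope)) {
      if (d > 0) gt <- gt + 1
      else if (d < 0) lt <- lt + 1
      else { gt <- gt + 0.5; lt <- lt + 0.5 }
    } else {
      if (d >= rope[1] && d <= rope[2]) eq <- eq + 1
      else if (d > rope[2]) gt <- gt + 1
      else lt <- lt + 1
    }
  }
  list(p_lt = lt / n, p_gt = gt / n,
       p_eq = if (is.null(rope)) NA_real_ else eq / n)
}

# naive multi-group largest/smallest enumeration with tie splitting
extremes_oracle <- function(sets) {
  k <- length(sets)
  n <- length(sets[[1]])
  largest <- smallest <- numeric(k)
  for (i in seq_len(n)) {
    v <- vapply(sets, `[[`, 0, i)
    mx <- which(v == max(v))
    mn <- which(v == min(v))
    largest[mx] <- largest[mx] + 1 / length(mx)
    smallest[mn] <- smallest[mn] + 1 / length(mn)
  }
  list(p_largest = largest / n, p_smallest = smallest / n)
}

# is angle theta inside the circular arc from lo to hi (all radians)?
angle_in_arc <- function(theta, lo, hi) {
  span <- (hi - lo) %% (2 * pi)
  off <- (theta - lo) %% (2 * pi)
  off <= span + 1e-12
}

# build a fit object with prescribed constant group-level draws (used to
# test posterior predictive machinery at known parameter values)
constant_fit <- function(class1, model, pars, values, n = 1000) {
  arr <- array(rep(values, each = n), c(1, n, length(pars)))
  bpsy:::new_bfit(model, class1, arr, pars, group_pars = pars,
                  subject_pars = character(), n_subjects = 0L,
                  data = list(), settings = sampler_settings(1, 0, n, 1),
                  priors = list())
}
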