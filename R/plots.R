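# Plotting layer. Every plot is a thin base-graphics rendering of a numeric
# "plot summary" payload; the payloads are pure functions of the draws and
# are what the tests exercise, so no image comparison is ever needed.

#' Numeric summary of a difference histogram
#'
#' Histogram of the aligned differences `a - b` together with the mean, the
#' 95% HDI band and (optionally) the ROPE band — the numeric payload behind
#' [plot_means_difference()].
#'
#' @param a,b aligned draw vectors.
#' @param rope optional `c(lower, upper)` region of practical equivalence.
#' @param bins number of histogram bins.
#' @return A list of class `bpsy_plot_summary` with fields `kind`,
#'   `breaks`, `counts` (summing to the number of draws), `mean`, `hdi`,
#'   `rope`.
#' @export
difference_summary <- function(a, b, rope = NULL, bins = 30) {
  if (length(a) != length(b))
    stop_alignment("draw vectors differ in length")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop_validation("'bins' must be positive")
  rope <- check_rope(rope)
  d <- a - b
  rng <- range(d)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- hist(d, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  hdi <- if (length(d) >= 2L) compute_hdi(d, 0.95)
         else list(lower = d, upper = d, mass = 0.95)
  structure(list(kind = "difference", breaks = h$breaks, counts = h$counts,
                 mean = mean(d), hdi = c(hdi$lower, hdi$upper), rope = rope),
            class = "bpsy_plot_summary")
}

#' Trace plot
#'
#' Draws the per-chain sampling traces of a parameter (all group-level
#' parameters if `parameter` is `NULL` uses the first), the standard visual
#' check of mixing and convergence.
#'
#' @param fit a fitted model object.
#' @param parameter parameter name (defaults to the first group-level one).
#' @param draw render the plot (set `FALSE` to only get the payload).
#' @return Invisibly, a `bpsy_plot_summary` payload with the per-chain
#'   series.
#' @export
plot_trace <- function(fit, parameter = NULL, draw = TRUE) {
  if (!inherits(fit, "bpsy_fit")) stop_validation("'fit' must be a bpsy fit")
  if (is.null(parameter)) parameter <- fit$group_pars[1]
  ch <- param_chains(fit$draws, parameter)
  payload <- structure(list(kind = "trace", parameter = parameter,
                            series = lapply(seq_len(nrow(ch)),
                                            function(i) ch[i, ])),
                       class = "bpsy_plot_summary")
  if (draw) {
    matplot(t(ch), type = "l", lty = 1, xlab = "iteration",
            ylab = parameter, main = sprintf("trace of %s", parameter))
  }
  invisible(payload)
}

#' Histogram of the difference between two fits' means
#'
#' Visualizes the distribution of the draw-aligned difference of the mean
#' parameters of two fits, with the mean (vertical line), the 95% HDI band
#' and the ROPE band at the bottom.
#'
#' @param fit1,fit2 fitted models (or draw vectors).
#' @param rope optional region of practical equivalence.
#' @param bins number of histogram bins.
#' @param par parameter selector, see [mean_draws_of()].
#' @param draw render the plot.
#' @return Invisibly, the [difference_summary()] payload.
#' @export
plot_means_difference <- function(fit1, fit2, rope = NULL, bins = 30,
                                  par = NULL, draw = TRUE) {
  a <- mean_draws_of(fit1, par = par)
  b <- mean_draws_of(fit2, par = par)
  payload <- difference_summary(a, b, rope = rope, bins = bins)
  if (draw) {
    d <- a - b
    hist(d, breaks = payload$breaks, main = "difference of means",
         xlab = "difference", col = "grey85", border = "white")
    abline(v = payload$mean, col = "blue", lwd = 2)
    y0 <- -0.02 * max(payload$counts)
    segments(payload$hdi[1], y0, payload$hdi[2], y0, lwd = 4)
    if (!is.null(payload$rope))
      segments(payload$rope[1], 2 * y0, payload$rope[2], 2 * y0,
               lwd = 4, col = "grey50")
  }
  invisible(payload)
}

#' Density of the mean draws of one or more fits
#'
#' @param ... fitted models or draw vectors.
#' @param par parameter selector, see [mean_draws_of()].
#' @param draw render the plot.
#' @return Invisibly, a `bpsy_plot_summary` with per-group density curves.
#' @export
plot_means <- function(..., par = NULL, draw = TRUE) {
  sets <- lapply(list(...), mean_draws_of, par = par)
  dens <- lapply(sets, function(x) {
    d <- stats::density(x)
    list(x = d$x, y = d$y)
  })
  payload <- structure(list(kind = "means", densities = dens),
                       class = "bpsy_plot_summary")
  if (draw) {
    xl <- range(unlist(lapply(dens, `[[`, "x")))
    yl <- c(0, max(unlist(lapply(dens, `[[`, "y"))))
    plot(NA, xlim = xl, ylim = yl, xlab = "mean", ylab = "density",
         main = "posterior means")
    for (i in seq_along(dens))
      lines(dens[[i]]$x, dens[[i]]$y, col = i, lwd = 2)
  }
  invisible(payload)
}

#' Fit-versus-data plot
#'
#' Overlays the posterior-mean data distribution on a histogram of the
#' input data (group level).
#'
#' @param fit a fitted model object.
#' @param draw render the plot.
#' @return Invisibly, a `bpsy_plot_summary` with the fitted density curve.
#' @export
plot_fit <- function(fit, draw = TRUE) {
  if (!inherits(fit, "bpsy_fit")) stop_validation("'fit' must be a bpsy fit")
  cf <- coef(fit)
  if (inherits(fit, "bpsy_ttest")) {
    xs <- fit$data$y
    grid <- seq(min(xs) - sd(xs), max(xs) + sd(xs), length.out = 200)
    dens <- exp(student_t_log_density(grid, cf["nu"], cf["mu"], cf["sigma"]))
  } else if (inherits(fit, "bpsy_reaction_time")) {
    xs <- fit$data$t
    grid <- seq(1e-3, max(xs) * 1.2, length.out = 200)
    dens <- exp(exgaussian_log_density(grid, cf["mu_mu"], cf["mu_sigma"],
                                       cf["mu_lambda"]))
  } else if (inherits(fit, "bpsy_linear")) {
    xs <- fit$data$y
    grid <- seq(min(xs) - sd(xs), max(xs) + sd(xs), length.out = 200)
    mid <- mean(range(fit$data$x))
    dens <- dnorm(grid, cf["mu_a"] + cf["mu_b"] * mid, cf["mu_s"])
  } else if (inherits(fit, "bpsy_success_rate")) {
    xs <- fit$data$r
    grid <- c(0, 1)
    dens <- c(1 - cf["p"], cf["p"])
  } else {
    stop_unsupported(sprintf("no fit plot for model '%s'", fit$model))
  }
  payload <- structure(list(kind = "fit", grid = grid, density = dens),
                       class = "bpsy_plot_summary")
  if (draw) {
    hist(xs, freq = FALSE, breaks = 30, col = "lightsteelblue",
         border = "white", main = sprintf("%s fit", fit$model), xlab = "data")
    lines(grid, dens, lwd = 2)
  }
  invisible(payload)
}

# circular HDI: recentre the angle draws around their circular mean, take
# the linear HDI there, and wrap the endpoints back
circular_hdi <- function(theta, mass = 0.95) {
  ctr <- circular_mean(theta)
  shifted <- wrap_angle_diff(theta - ctr)
  h <- compute_hdi(shifted, mass)
  c(lower = (h$lower + ctr) %% (2 * pi), upper = (h$upper + ctr) %% (2 * pi))
}

#' Color-wheel summary of a color fit
#'
#' The numeric payload of the color-wheel visualization: the posterior mean
#' hue angle and the circular HDI band of the hue location draws, in
#' degrees, plus pass-through annotation slots for external reference hues
#' (e.g. hues predicted by competing color-coding theories).
#'
#' @param fit a [b_color()] fit.
#' @param mass HDI mass.
#' @param annotations optional numeric vector of reference hues (degrees),
#'   carried through unchanged.
#' @return A `bpsy_plot_summary` with fields `mean_deg`, `hdi_deg`
#'   (`lower`/`upper`, respecting wraparound), `mass`, `annotations`.
#' @export
color_wheel_summary <- function(fit, mass = 0.95, annotations = NULL) {
  if (!inherits(fit, "bpsy_color"))
    stop_validation("'fit' must come from b_color()")
  theta <- extract_group_draws(fit, "mu_h")
  band <- circular_hdi(theta, mass) * 180 / pi
  structure(list(kind = "color_wheel",
                 mean_deg = circular_mean(theta) * 180 / pi,
                 hdi_deg = c(lower = unname(band[1]),
                             upper = unname(band[2])),
                 mass = mass, annotations = annotations),
            class = "bpsy_plot_summary")
}

#' Color-wheel plot of hue posterior
#'
#' Renders [color_wheel_summary()]: the mean hue as a solid radius, the
#' circular HDI as an arc band, and any annotation hues as dashed radii.
#'
#' @inheritParams color_wheel_summary
#' @param draw render the plot.
#' @return Invisibly, the payload.
#' @export
plot_color_wheel <- function(fit, mass = 0.95, annotations = NULL,
                             draw = TRUE) {
  payload <- color_wheel_summary(fit, mass, annotations)
  if (draw) {
    plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
         axes = FALSE, xlab = "", ylab = "", main = "hue posterior")
    ang <- seq(0, 2 * pi, length.out = 360)
    lines(cos(ang), sin(ang), col = "grey70")
    lo <- payload$hdi_deg["lower"] * pi / 180
    hi <- payload$hdi_deg["upper"] * pi / 180
    span <- (hi - lo) %% (2 * pi)
    arc <- lo + seq(0, span, length.out = 100)
    lines(1.05 * cos(arc), 1.05 * sin(arc), lwd = 4, col = "grey40")
    m <- payload$mean_deg * pi / 180
    segments(0, 0, cos(m), sin(m), lwd = 2)
    for (a in payload$annotations) {
      ar <- a * pi / 180
      segments(0, 0, cos(ar), sin(ar), lty = 2)
    }
  }
  invisible(payload)
}

#' @export
print.bpsy_plot_summary <- function(x, ...) {
  cat(sprintf("plot summary: %s\n", x$kind))
  str <- utils::capture.output(utils::str(unclass(x), max.level = 1))
  cat(str, sep = "\n")
  invisible(x)
}
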