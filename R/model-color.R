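#' RGB to HSV conversion
#'
#' Standard hexcone conversion (via [grDevices::rgb2hsv()]): value is
#' `max/255`, saturation `(max - min)/max` (0 for black), hue the sector
#' angle in degrees in `[0, 360)` with the convention hue = 0 whenever
#' saturation is 0.
#'
#' @param r,g,b integer components in `[0, 255]`, vectorized.
#' @return A `data.frame` with columns `h` (degrees), `s`, `v`.
#' @export
#' @examples
#' rgb_to_hsv(255, 0, 0) # pure red: h = 0, s = 1, v = 1
rgb_to_hsv <- function(r, g, b) {
  comp <- cbind(r, g, b)
  if (anyNA(comp) || any(comp < 0) || any(comp > 255))
    stop_validation("RGB components must lie in [0, 255]")
  m <- grDevices::rgb2hsv(t(comp), maxColorValue = 255)
  data.frame(h = (m["h", ] * 360) %% 360, s = m["s", ], v = m["v", ],
             row.names = NULL)
}

#' HSV to RGB conversion
#'
#' Inverse of [rgb_to_hsv()]; components are returned as integers in
#' `[0, 255]` (rounded).
#'
#' @param h hue in degrees.
#' @param s,v saturation and value in `[0, 1]`.
#' @return A `data.frame` with integer columns `r`, `g`, `b`.
#' @export
hsv_to_rgb <- function(h, s, v) {
  if (anyNA(c(h, s, v)) || any(s < 0 | s > 1) || any(v < 0 | v > 1))
    stop_validation("'s' and 'v' must lie in [0, 1]")
  cols <- grDevices::hsv((h %% 360) / 360, s, v)
  m <- grDevices::col2rgb(cols)
  data.frame(r = as.integer(m["red", ]), g = as.integer(m["green", ]),
             b = as.integer(m["blue", ]), row.names = NULL)
}

#' Log density of the von Mises distribution
#'
#' The circular analog of the normal distribution:
#' `kappa * cos(theta - mu) - log(2 * pi * I0(kappa))`. `kappa = 0` is the
#' circular uniform; the density is periodic in `theta` with period `2*pi`.
#'
#' @param theta angle(s) in radians.
#' @param mu mean direction in radians.
#' @param kappa concentration, >= 0.
#' @return Log density, vectorized over `theta`.
#' @export
#' @examples
#' von_mises_log_density(0, 0, 0) # log(1 / (2*pi))
von_mises_log_density <- function(theta, mu, kappa) {
  if (!is.finite(kappa) || kappa < 0) stop_domain("'kappa' must be >= 0")
  .vm_lpdf_cpp(as.numeric(theta), mu, kappa)
}

#' Circular mean of a set of angles
#'
#' The direction of the mean resultant vector, wrapped to `[0, 2*pi)`. The
#' mean is undefined when the resultant length is (numerically) zero, e.g.
#' for an antipodal pair of angles.
#'
#' @param angles numeric vector of angles in radians.
#' @param tol resultant-length tolerance below which the mean is undefined.
#' @return The circular mean in radians.
#' @export
#' @examples
#' circular_mean(c(350, 10) * pi / 180) # 0
circular_mean <- function(angles, tol = 1e-8) {
  if (!is.numeric(angles) || !length(angles))
    stop_validation("'angles' must be a non-empty numeric vector")
  cm <- mean(cos(angles)); sm <- mean(sin(angles))
  if (sqrt(cm^2 + sm^2) < tol)
    stop_degenerate("circular mean undefined: resultant length is ~0")
  w <- atan2(sm, cm) %% (2 * pi)
  if (2 * pi - w < 1e-9) w <- 0
  w
}

# shortest wrapped angular difference, in (-period/2, period/2]
wrap_angle_diff <- function(d, period = 2 * pi) {
  half <- period / 2
  out <- (d + half) %% period - half
  out[out == -half] <- half
  out
}

#' Bayesian color model
#'
#' Component-wise model of color responses: normal distributions truncated
#' to `[0, 255]` for the R, G and B components, `[0, 1]`-truncated normals
#' for saturation and value, and a von Mises distribution for the circular
#' hue component. The color space not supplied is derived row-wise via the
#' RGB/HSV conversion, then the six components are fitted independently
#' (the truncated-normal likelihood includes its normalizing constant).
#'
#' Hue is modeled in radians internally and reported in degrees at the
#' interface; comparisons of hue use the wrapped difference in `(-pi, pi]`.
#'
#' @param data three-column matrix or data.frame of color triplets: integer
#'   RGB in `[0, 255]`, or HSV (hue in degrees, `s`/`v` in `[0, 1]`) with
#'   `hsv = TRUE`.
#' @param hsv logical; is the input HSV?
#' @param chains,warmup,iter,seed sampler settings, see [sampler_settings()].
#' @return An object of class `c("bpsy_color", "bpsy_fit")` with group-level
#'   parameters `mu_r`, `sigma_r`, `mu_g`, `sigma_g`, `mu_b`, `sigma_b`,
#'   `mu_s`, `sigma_s`, `mu_v`, `sigma_v`, `mu_h` (radians), `kappa_h`.
#' @export
b_color <- function(data, hsv = FALSE, chains = 4, warmup = 1000,
                    iter = 1000, seed = NULL) {
  data <- as.data.frame(data)
  if (ncol(data) != 3L)
    stop_validation("'data' must have exactly three columns")
  if (nrow(data) < 2L)
    stop_validation("at least 2 color observations are required")
  if (anyNA(data) || any(!vapply(data, is.numeric, TRUE)))
    stop_validation("'data' must be numeric and complete")
  if (hsv) {
    h <- data[[1]]; s <- data[[2]]; v <- data[[3]]
    if (any(h < 0 | h >= 360))
      stop_validation("hue must lie in [0, 360) degrees")
    if (any(s < 0 | s > 1) || any(v < 0 | v > 1))
      stop_validation("saturation and value must lie in [0, 1]")
    rgb <- hsv_to_rgb(h, s, v)
  } else {
    rgb <- data; names(rgb) <- c("r", "g", "b")
    if (any(rgb < 0) || any(rgb > 255))
      stop_validation("RGB components must lie in [0, 255]")
    hh <- rgb_to_hsv(rgb$r, rgb$g, rgb$b)
    h <- hh$h; s <- hh$s; v <- hh$v
  }
  comp <- list(r = list(x = rgb$r, lo = 0, hi = 255),
               g = list(x = rgb$g, lo = 0, hi = 255),
               b = list(x = rgb$b, lo = 0, hi = 255),
               s = list(x = s, lo = 0, hi = 1),
               v = list(x = v, lo = 0, hi = 1))
  for (nm in names(comp))
    if (sd(comp[[nm]]$x) == 0)
      stop_degenerate(sprintf(
        "component '%s' is constant; add variation or jitter the data", nm))
  theta <- h * pi / 180
  settings <- sampler_settings(chains, warmup, iter, seed)

  n_par <- 12L
  run_chain_all <- function(chain) {
    cols <- vector("list", 6L)
    for (j in seq_along(comp)) {
      ci <- comp[[j]]
      init <- c(mean(ci$x) + 0.1 * sd(ci$x) * rnorm(1),
                sd(ci$x) * exp(0.1 * rnorm(1)))
      cols[[j]] <- .chain_tnorm_cpp(ci$x, ci$lo, ci$hi,
                                    settings$warmup, settings$iter, init)
    }
    mu0 <- circular_mean(theta)
    rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
    k0 <- max(rbar * (2 - rbar^2) / max(1 - rbar^2, 1e-6), 0.05)
    init_vm <- c((mu0 + 0.1 * rnorm(1)) %% (2 * pi), k0 * exp(0.2 * rnorm(1)))
    cols[[6]] <- .chain_vm_cpp(theta, settings$warmup, settings$iter, init_vm)
    do.call(cbind, cols)
  }
  values <- run_chains(settings, run_chain_all, n_par)
  par_names <- c("mu_r", "sigma_r", "mu_g", "sigma_g", "mu_b", "sigma_b",
                 "mu_s", "sigma_s", "mu_v", "sigma_v", "mu_h", "kappa_h")
  new_bfit("color", "bpsy_color", values, par_names,
           group_pars = par_names, subject_pars = character(),
           n_subjects = 0L,
           data = list(rgb = rgb, h = h, s = s, v = v),
           settings = settings, priors = list())
}
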