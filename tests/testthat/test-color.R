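test_that("RGB to HSV follows the hexcone conventions", {
  red <- rgb_to_hsv(255, 0, 0)
  expect_equal(unlist(red), c(h = 0, s = 1, v = 1))
  black <- rgb_to_hsv(0, 0, 0)
  expect_equal(unlist(black), c(h = 0, s = 0, v = 0)) # s=0 => hue 0
  grey <- rgb_to_hsv(128, 128, 128)
  expect_equal(grey$v, 128 / 255, tolerance = 1e-12)
  expect_equal(grey$s, 0)
  expect_error(rgb_to_hsv(300, 0, 0), class = "bpsy_validation_error")
})

test_that("RGB <-> HSV round-trips on a 6-bit-per-channel grid", {
  lv <- seq(0, 252, by = 4)  # 64 levels per channel
  g <- expand.grid(r = lv, g = lv, b = lv)
  hsv <- rgb_to_hsv(g$r, g$g, g$b)
  back <- hsv_to_rgb(hsv$h, hsv$s, hsv$v)
  expect_lte(max(abs(back$r - g$r)), 1)
  expect_lte(max(abs(back$g - g$g)), 1)
  expect_lte(max(abs(back$b - g$b)), 1)
})

test_that("von Mises log density matches closed forms and is periodic", {
  expect_equal(von_mises_log_density(1.3, 0.2, 0), log(1 / (2 * pi)),
               tolerance = 1e-12)
  at_mode <- von_mises_log_density(0.7, 0.7, 1)
  expect_equal(at_mode, 1 - log(2 * pi * besselI(1, 0)), tolerance = 1e-10)
  expect_lt(abs(at_mode - (-1.0738)), 1e-4)
  expect_equal(von_mises_log_density(0.5, 0.1, 3),
               von_mises_log_density(0.5 + 2 * pi, 0.1, 3), tolerance = 1e-10)
  expect_error(von_mises_log_density(0, 0, -1), class = "bpsy_domain_error")
})

test_that("circular mean wraps and detects undefined cases", {
  expect_equal(circular_mean(c(350, 10) * pi / 180), 0, tolerance = 1e-10)
  expect_equal(circular_mean(c(10, 20, 30) * pi / 180), 20 * pi / 180,
               tolerance = 1e-9)
  expect_error(circular_mean(c(0, pi)), class = "bpsy_degenerate_error")
})

test_that("hue location and concentration are recovered", {
  set.seed(61)
  n <- 500
  h <- (bpsy:::rvonmises(n, 0.1, 20) * 180 / pi) %% 360
  s <- bpsy:::rtruncnorm(n, 0.9, 0.05, 0, 1)
  v <- bpsy:::rtruncnorm(n, 0.9, 0.05, 0, 1)
  f <- fit_quick(b_color, data.frame(h = h, s = s, v = v), hsv = TRUE,
                 seed = 61)
  band <- bpsy:::circular_hdi(extract_group_draws(f, "mu_h"), 0.95)
  expect_true(angle_in_arc(0.1, band["lower"], band["upper"]))
  kap <- mean(extract_group_draws(f, "kappa_h"))
  expect_gt(kap, 10); expect_lt(kap, 40)
})

test_that("hue fitting is rotation equivariant", {
  set.seed(62)
  n <- 300
  h0 <- (bpsy:::rvonmises(n, 1.0, 25) * 180 / pi) %% 360
  s <- rep(0.9, n) + rnorm(n, 0, 0.02)
  v <- rep(0.9, n) + rnorm(n, 0, 0.02)
  delta <- 2.0 # radians
  f0 <- fit_quick(b_color, data.frame(h = h0, s = s, v = v), hsv = TRUE,
                  seed = 62)
  f1 <- fit_quick(b_color,
                  data.frame(h = (h0 + delta * 180 / pi) %% 360, s = s, v = v),
                  hsv = TRUE, seed = 62)
  m0 <- circular_mean(extract_group_draws(f0, "mu_h"))
  m1 <- circular_mean(extract_group_draws(f1, "mu_h"))
  shift <- bpsy:::wrap_angle_diff(m1 - m0)
  expect_lt(abs(shift - delta), 0.1)
})

test_that("truncated-normal likelihood integrates to one", {
  for (pars in list(c(128, 30, 0, 255), c(240, 60, 0, 255),
                    c(0.9, 0.2, 0, 1))) {
    f <- function(x) exp(bpsy:::.tnorm_lpdf_cpp(x, pars[1], pars[2],
                                                pars[3], pars[4]))
    q <- integrate(f, pars[3], pars[4], rel.tol = 1e-10)
    expect_lt(abs(q$value - 1), 1e-8)
  }
})

test_that("components far from the bounds match the untruncated posterior", {
  set.seed(63)
  n <- 200
  r <- pmin(pmax(round(rnorm(n, 128, 10)), 0), 255)
  g <- pmin(pmax(round(rnorm(n, 100, 12)), 0), 255)
  b <- pmin(pmax(round(rnorm(n, 90, 8)), 0), 255)
  f <- fit_quick(b_color, data.frame(r = r, g = g, b = b), seed = 63)
  rep <- summarize_fit(f)
  row <- rep[rep$parameter == "mu_r", ]
  # flat-prior normal-mean posterior is centred at the sample mean
  expect_lt(abs(row$mean - mean(r)), 3 * row$se_mean + 0.5)
})

test_that("color input validation and degenerate data", {
  expect_error(b_color(data.frame(r = c(1, 2))),
               class = "bpsy_validation_error")
  expect_error(b_color(data.frame(r = 300, g = 0, b = 0)),
               class = "bpsy_validation_error")
  expect_error(b_color(data.frame(h = c(10, 20), s = c(2, 0.5),
                                  v = c(0.5, 0.5)), hsv = TRUE),
               class = "bpsy_validation_error")
  same <- data.frame(r = rep(10, 5), g = rep(20, 5), b = rep(30, 5))
  expect_error(b_color(same), class = "bpsy_degenerate_error")
})

test_that("color wheel summary respects wraparound", {
  # constant hue draws at 120 degrees: zero-width band at the mean
  arr <- array(rep(c(120 * pi / 180, 5), each = 400), c(1, 400, 2))
  f <- bpsy:::new_bfit("color", "bpsy_color", arr, c("mu_h", "kappa_h"),
                       group_pars = c("mu_h", "kappa_h"),
                       subject_pars = character(), n_subjects = 0L,
                       data = list(), settings = sampler_settings(1, 0, 400, 1),
                       priors = list())
  cw <- color_wheel_summary(f)
  expect_equal(cw$mean_deg, 120, tolerance = 1e-9)
  expect_equal(unname(cw$hdi_deg["lower"]), 120, tolerance = 1e-9)
  expect_equal(unname(cw$hdi_deg["upper"]), 120, tolerance = 1e-9)

  # draws straddling 0/360: the band must contain the mean near 0
  set.seed(64)
  th <- (bpsy:::rvonmises(2000, 0.02, 50)) %% (2 * pi)
  band <- bpsy:::circular_hdi(th, 0.95)
  expect_true(angle_in_arc(0.02, band["lower"], band["upper"]))
  expect_true(band["lower"] > band["upper"]) # wraps through zero

  # annotations pass through unchanged
  cw2 <- color_wheel_summary(f, annotations = c(0, 180))
  expect_identical(cw2$annotations, c(0, 180))
})

test_that("hue mean draws compare in degrees across the 0/360 seam", {
  mk <- function(h_deg) {
    arr <- array(rep(c(h_deg * pi / 180, 10), each = 100), c(1, 100, 2))
    bpsy:::new_bfit("color", "bpsy_color", arr, c("mu_h", "kappa_h"),
                    group_pars = c("mu_h", "kappa_h"),
                    subject_pars = character(), n_subjects = 0L,
                    data = list(), settings = sampler_settings(1, 0, 100, 1),
                    priors = list())
  }
  d <- mean_draws_of(mk(359), par = "h")
  expect_equal(unname(d[1]), 359)
  expect_identical(attr(d, "period"), 360)
  # 359 vs 1 degrees: wrapped difference is -2, inside a 5-degree ROPE
  cmp <- compare_means(mk(359), mk(1), par = "h", rope = c(-5, 5))
  expect_identical(cmp$pairs$p_equal, 1)
  expect_equal(c(cmp$pairs$hdi_lower, cmp$pairs$hdi_upper), c(-2, -2))
})
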