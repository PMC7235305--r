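# Seeded generators emulating the structure of four classic experiments
# (flanker, adaptation level, Stroop, afterimages) so every workflow runs
# end-to-end with known ground truth. The emitted tables validate directly
# against the matching model's input schema, and each carries its generating
# parameters in attr(, "ground_truth") and seed in attr(, "seed").

new_synth <- function(x, ground_truth, seed) {
  attr(x, "ground_truth") <- ground_truth
  attr(x, "seed") <- seed
  x
}

#' Ground truth of a synthetic dataset
#'
#' @param x an object produced by one of the `generate_*()` functions.
#' @return The list of generating parameters recorded at generation time.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Synthetic flanker-task data
#'
#' Emulates a two-group flanker experiment: per-subject exGaussian reaction
#' times with group-level normal variation, the test group's group-level
#' `mu_mu` shifted by `group_shift` seconds, plus per-subject Bernoulli
#' correctness with a group-specific correct rate. Defaults give a control
#' group at `mu_mu = 0.35 s`, `mu_lambda = 8` (mean RT about 0.475 s) and a
#' 0.05 s test-group shift.
#'
#' @param n_per_group subjects per group.
#' @param trials trials per subject.
#' @param group_shift shift of the test group's `mu_mu`, seconds.
#' @param error_rate_gap drop in the test group's correct-response rate.
#' @param seed integer seed; drawn and recorded if `NULL`.
#' @param raw_ids emit non-contiguous subject ids (control group offset the
#'   way raw lab exports often are) to exercise the re-indexing validation.
#' @return A list with elements `rt` (data.frame `group`, `subject`,
#'   `correct`, `rt`) and `success` (data.frame `group`, `subject`,
#'   `result`), with ground truth and seed attributes.
#' @export
generate_flanker <- function(n_per_group = 22, trials = 80,
                             group_shift = 0.05, error_rate_gap = 0.05,
                             seed = NULL, raw_ids = FALSE) {
  if (n_per_group < 1 || trials < 1)
    stop_validation("'n_per_group' and 'trials' must be positive")
  if (error_rate_gap <= 0 || error_rate_gap >= 1)
    stop_validation("'error_rate_gap' must be in (0, 1)")
  truth <- list(
    control = list(mu_mu = 0.35, sigma_mu = 0.05, mu_sigma = 0.06,
                   sigma_sigma = 0.015, mu_lambda = 8, sigma_lambda = 1.5,
                   p_correct = 0.95),
    test = list(mu_mu = 0.35 + group_shift, sigma_mu = 0.05, mu_sigma = 0.06,
                sigma_sigma = 0.015, mu_lambda = 8, sigma_lambda = 1.5,
                p_correct = 0.95 - error_rate_gap),
    group_shift = group_shift)
  if (truth$test$mu_mu <= 0.01)
    stop_validation("'group_shift' would push reaction times to zero or below")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  set.seed(seed)

  one_group <- function(g, pars) {
    mu_i <- rtruncnorm(n_per_group, pars$mu_mu, pars$sigma_mu, 0.01, Inf)
    sg_i <- rtruncnorm(n_per_group, pars$mu_sigma, pars$sigma_sigma, 1e-3, Inf)
    lm_i <- rtruncnorm(n_per_group, pars$mu_lambda, pars$sigma_lambda, 0.1, Inf)
    subj <- rep(seq_len(n_per_group), each = trials)
    t <- rnorm(n_per_group * trials, mu_i[subj], sg_i[subj]) +
      rexp(n_per_group * trials, rate = lm_i[subj])
    t <- pmax(t, 0.01)
    correct <- rbinom(n_per_group * trials, 1L, pars$p_correct)
    list(rt = data.frame(group = g, subject = subj, correct = correct, rt = t),
         success = data.frame(group = g, subject = subj, result = correct))
  }
  ctrl <- one_group("control", truth$control)
  test <- one_group("test", truth$test)
  rt <- rbind(ctrl$rt, test$rt)
  success <- rbind(ctrl$success, test$success)
  if (raw_ids) {
    off <- which(rt$group == "control")
    rt$subject[off] <- rt$subject[off] + 21L
    off <- which(success$group == "control")
    success$subject[off] <- success$subject[off] + 21L
  }
  new_synth(list(rt = rt, success = success), truth, seed)
}

#' Synthetic adaptation-level data
#'
#' Emulates the second phase of a weight-assessment experiment: two groups
#' judge the same medium weights after adapting to light vs. heavy sets, so
#' their per-subject linear trends start from different intercepts and decay
#' toward each other. Subject intercepts and slopes vary around the group
#' values; responses stay continuous on the 9-point assessment scale.
#'
#' @param n_per_group subjects per group.
#' @param n_trials measurements per subject (the independent variable runs
#'   1..`n_trials`).
#' @param intercepts group intercepts (light-adapted, heavy-adapted).
#' @param slopes group slopes.
#' @param noise_sd residual standard deviation, > 0.
#' @param seed integer seed; drawn and recorded if `NULL`.
#' @return A data.frame with columns `group`, `subject`, `sequence`,
#'   `response`, with ground truth and seed attributes.
#' @export
generate_adaptation <- function(n_per_group = 20, n_trials = 10,
                                intercepts = c(8.0, 5.8),
                                slopes = c(-0.11, 0.12),
                                noise_sd = 1, seed = NULL) {
  if (n_trials < 2) stop_validation("'n_trials' must be at least 2")
  if (noise_sd <= 0) stop_validation("'noise_sd' must be positive")
  truth <- list(intercepts = intercepts, slopes = slopes,
                sigma_alpha = 0.5, sigma_beta = 0.04, noise_sd = noise_sd)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  set.seed(seed)
  rows <- lapply(1:2, function(g) {
    a_i <- rnorm(n_per_group, intercepts[g], truth$sigma_alpha)
    b_i <- rnorm(n_per_group, slopes[g], truth$sigma_beta)
    subj <- rep(seq_len(n_per_group), each = n_trials)
    x <- rep(seq_len(n_trials), n_per_group)
    y <- a_i[subj] + b_i[subj] * x + rnorm(length(x), 0, noise_sd)
    data.frame(group = g, subject = subj, sequence = x, response = y)
  })
  new_synth(do.call(rbind, rows), truth, seed)
}

#' Synthetic Stroop data
#'
#' Emulates a four-condition Stroop sheet-completion experiment with a
#' paired layout: each subject completes every condition once, and times
#' combine a subject random effect with the condition mean. Default
#' condition means (43, 46, 55, 69 seconds) are ordered reading-neutral <
#' reading-incongruent < naming-neutral < naming-incongruent.
#'
#' @param n_subjects number of subjects.
#' @param condition_means completion-time means in seconds for the four
#'   conditions (reading neutral, reading incongruent, naming neutral,
#'   naming incongruent).
#' @param within_subject_sd residual sd of a single completion time.
#' @param between_subject_sd sd of the subject random effect.
#' @param seed integer seed; drawn and recorded if `NULL`.
#' @return A data.frame with columns `subject`, `condition`, `time`
#'   (one row per subject per condition), with ground truth and seed
#'   attributes.
#' @export
generate_stroop <- function(n_subjects = 30,
                            condition_means = c(43, 46, 55, 69),
                            within_subject_sd = 2, between_subject_sd = 8,
                            seed = NULL) {
  if (any(condition_means <= 0))
    stop_validation("'condition_means' must be positive")
  if (within_subject_sd <= 0 || between_subject_sd <= 0)
    stop_validation("standard deviations must be positive")
  truth <- list(condition_means = condition_means,
                within_subject_sd = within_subject_sd,
                between_subject_sd = between_subject_sd)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  set.seed(seed)
  cond_names <- c("reading_neutral", "reading_incongruent",
                  "naming_neutral", "naming_incongruent")
  u <- rnorm(n_subjects, 0, between_subject_sd)
  rows <- lapply(seq_along(condition_means), function(c) {
    data.frame(subject = seq_len(n_subjects), condition = cond_names[c],
               time = condition_means[c] + u +
                 rnorm(n_subjects, 0, within_subject_sd))
  })
  new_synth(do.call(rbind, rows), truth, seed)
}

# default six-stimulus palette for the afterimage generator
default_stimuli <- function() {
  data.frame(stimulus = c("red", "green", "blue", "cyan", "magenta", "yellow"),
             r = c(255, 0, 0, 0, 255, 255),
             g = c(0, 255, 0, 255, 0, 255),
             b = c(0, 0, 255, 255, 255, 0))
}

#' Synthetic afterimage data
#'
#' Emulates color-matching responses to colored stimuli: response hues are
#' von Mises distributed around each stimulus hue plus `hue_offset`
#' (`hue_offset = pi` emulates complementary, opponent-style responses),
#' saturation and value are truncated normals near the upper end of
#' `[0, 1]`, and the responses are returned in RGB.
#'
#' @param n_responses_per_stimulus responses per stimulus.
#' @param stimuli data.frame with columns `stimulus`, `r`, `g`, `b`.
#' @param hue_kappa von Mises concentration of the response hues, > 0.
#' @param hue_offset offset added to each stimulus hue, radians.
#' @param seed integer seed; drawn and recorded if `NULL`.
#' @return A data.frame with columns `stimulus`, `r`, `g`, `b`, with ground
#'   truth (per-stimulus response hue in radians and degrees) and seed
#'   attributes.
#' @export
generate_afterimages <- function(n_responses_per_stimulus = 50,
                                 stimuli = default_stimuli(),
                                 hue_kappa = 30, hue_offset = 0,
                                 seed = NULL) {
  if (!nrow(stimuli)) stop_validation("'stimuli' must contain at least one row")
  if (hue_kappa <= 0) stop_validation("'hue_kappa' must be positive")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  set.seed(seed)
  stim_hsv <- rgb_to_hsv(stimuli$r, stimuli$g, stimuli$b)
  target_rad <- (stim_hsv$h * pi / 180 + hue_offset) %% (2 * pi)
  rows <- lapply(seq_len(nrow(stimuli)), function(i) {
    n <- n_responses_per_stimulus
    h <- rvonmises(n, target_rad[i], hue_kappa) * 180 / pi
    s <- rtruncnorm(n, 0.85, 0.1, 0, 1)
    v <- rtruncnorm(n, 0.85, 0.1, 0, 1)
    cbind(data.frame(stimulus = stimuli$stimulus[i]),
          hsv_to_rgb(h %% 360, s, v))
  })
  truth <- list(stimuli = stimuli, hue_kappa = hue_kappa,
                hue_offset = hue_offset,
                response_hue_rad = setNames(target_rad, stimuli$stimulus),
                response_hue_deg = setNames(target_rad * 180 / pi,
                                            stimuli$stimulus),
                sat_mean = 0.85, val_mean = 0.85, sat_val_sd = 0.1)
  new_synth(do.call(rbind, rows), truth, seed)
}
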