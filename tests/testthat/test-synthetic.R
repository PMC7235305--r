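test_that("generators are reproducible from their seed", {
  f1 <- generate_flanker(seed = 1); f2 <- generate_flanker(seed = 1)
  expect_identical(f1$rt, f2$rt)
  expect_identical(f1$success, f2$success)
  a1 <- generate_adaptation(seed = 2); a2 <- generate_adaptation(seed = 2)
  expect_identical(a1, a2)
  s1 <- generate_stroop(seed = 3); s2 <- generate_stroop(seed = 3)
  expect_identical(s1, s2)
  i1 <- generate_afterimages(seed = 4); i2 <- generate_afterimages(seed = 4)
  expect_identical(i1, i2)
})

test_that("generated tables satisfy the model input schemas", {
  f <- generate_flanker(n_per_group = 4, trials = 10, seed = 5)
  ctrl <- f$rt[f$rt$group == "control", ]
  expect_true(all(ctrl$rt > 0))
  expect_identical(sort(unique(ctrl$subject)), 1:4)
  expect_true(all(f$success$result %in% c(0, 1)))

  a <- generate_adaptation(n_per_group = 3, seed = 6)
  g1 <- a[a$group == 1, ]
  expect_identical(sort(unique(g1$subject)), 1:3)
  expect_identical(sort(unique(g1$sequence)), 1:10)

  s <- generate_stroop(n_subjects = 5, seed = 7)
  expect_identical(nrow(s), 20L) # paired: 5 subjects x 4 conditions
  expect_identical(length(unique(s$condition)), 4L)

  i <- generate_afterimages(n_responses_per_stimulus = 5, seed = 8)
  expect_identical(nrow(i), 30L)
  expect_true(all(i$r >= 0 & i$r <= 255))
  expect_true(all(c("stimulus", "r", "g", "b") %in% names(i)))
})

test_that("ground truth and seed are recorded", {
  f <- generate_flanker(seed = 9)
  gt <- ground_truth(f)
  expect_identical(gt$control$mu_mu, 0.35)
  expect_equal(gt$test$mu_mu - gt$control$mu_mu, 0.05)
  expect_identical(attr(f, "seed"), 9L)
  ai <- generate_afterimages(seed = 10)
  expect_identical(unname(ground_truth(ai)$response_hue_deg["red"]), 0)
  expect_equal(unname(ground_truth(ai)$response_hue_deg["cyan"]), 180)
})

test_that("raw ids exercise the contiguity validation path", {
  f <- generate_flanker(n_per_group = 3, trials = 5, seed = 11,
                        raw_ids = TRUE)
  ctrl <- f$rt[f$rt$group == "control", ]
  expect_identical(min(ctrl$subject), 22L)
  expect_error(b_reaction_time(ctrl$rt, ctrl$subject),
               class = "bpsy_validation_error")
  # re-indexing repairs it
  s2 <- as.integer(factor(ctrl$subject))
  expect_s3_class(b_reaction_time(ctrl$rt, s2, chains = 1, warmup = 50,
                                  iter = 50, seed = 1), "bpsy_fit")
})

test_that("generator validation rejects impossible settings", {
  expect_error(generate_flanker(group_shift = -0.5),
               class = "bpsy_validation_error")
  expect_error(generate_adaptation(noise_sd = 0),
               class = "bpsy_validation_error")
  expect_error(generate_stroop(condition_means = c(-1, 2, 3, 4)),
               class = "bpsy_validation_error")
  expect_error(generate_afterimages(hue_kappa = 0),
               class = "bpsy_validation_error")
})

test_that("null flanker shift yields an undecided comparison", {
  # with no true shift, P(control < test) behaves like a null p-value:
  # near-uniform across generator seeds, so its seed-average sits near 1/2
  probs <- vapply(1:6, function(k) {
    d <- generate_flanker(n_per_group = 10, trials = 40, group_shift = 0,
                          seed = 120 + k)
    rt <- d$rt[d$rt$correct == 1, ]
    fits <- lapply(c("control", "test"), function(g) {
      gd <- rt[rt$group == g, ]
      b_reaction_time(gd$rt, gd$subject, chains = 2, warmup = 300,
                      iter = 300, seed = 120 + k)
    })
    compare_means(fits[[1]], fits[[2]])$pairs$p_smaller
  }, 0)
  expect_gt(mean(probs), 0.2); expect_lt(mean(probs), 0.8)
  expect_gt(sum(probs > 0.05 & probs < 0.95), 2)
})
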