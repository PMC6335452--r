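test_that("independence GEE reproduces ordinary logistic regression", {
  d <- simulate_null_achievement(12, reps = 3, seed = 7)
  d$achieved <- as.numeric(d$achieved_LR)
  d$trial_type <- factor(d$trial_type, levels = c("standard",
                                                  "precommitment"))
  d$cost <- factor(d$cost_level)
  g <- gee_logit(achieved ~ trial_type + cost, d, id = d$subject_id,
                 corstr = "independence")
  gl <- stats::glm(achieved ~ trial_type + cost, binomial, d)
  expect_equal(unname(g$coefficients), unname(coef(gl)), tolerance = 1e-10)
  vc <- sandwich::vcovCL(gl, cluster = d$subject_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(g$vcov), unname(vc), tolerance = 1e-6)
})

test_that("exchangeable GEE matches an independent implementation", {
  # frozen oracle: statsmodels GEE (Binomial, Exchangeable) on this exact
  # fixture
  d <- simulate_null_achievement(12, reps = 3, seed = 7)
  d$achieved <- as.numeric(d$achieved_LR)
  d$trial_type <- factor(d$trial_type, levels = c("standard",
                                                  "precommitment"))
  d$cost <- factor(d$cost_level)
  g <- gee_logit(achieved ~ trial_type + cost, d, id = d$subject_id,
                 corstr = "exchangeable")
  expect_equal(unname(g$coefficients),
               c(1.48591318, -0.12835048, -1.08565005, -1.47808279),
               tolerance = 1e-6)
  expect_equal(g$alpha, 0.14153104, tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(g$vcov))),
               c(0.49459513, 0.21435576, 0.44524777, 0.45739844),
               tolerance = 1e-6)
})

test_that("achievement regression selects the minimum-QIC correlation", {
  d <- simulate_null_achievement(15, reps = 3, seed = 19)
  r <- achievement_regression(d, "effort")
  expect_equal(unname(r$qic[r$working_correlation]), min(r$qic))
  expect_setequal(r$wald$term, c("trial_type", "cost"))
  expect_true(all(r$cells$prob >= 0 & r$cells$prob <= 1))
  expect_equal(nrow(r$cells), 6)
  # the interaction variant is constructible and QIC-comparable
  ri <- achievement_regression(d, "effort", interaction = TRUE)
  expect_true("trial_type:cost" %in% ri$wald$term)
  expect_true(is.finite(min(ri$qic)))
})

test_that("steep discounting yields achievement decreasing in cost", {
  pc <- point_prior_config(discount = 0.5, gamma = 4, b_mean = -1)
  ch <- simulate_cohort(15, tasks = "effort", prior_config = pc, seed = 33)
  r <- achievement_regression(ch$trials, "effort")
  for (tt in c("standard", "precommitment")) {
    p <- r$cells$prob[r$cells$trial_type == tt]
    expect_true(all(diff(p) < 0))
  }
})

test_that("degenerate regression inputs error", {
  d <- simulate_null_achievement(5, reps = 2, seed = 3)
  expect_error(achievement_regression(d[d$subject_id == "s001", ], "effort"),
               "2 subjects")
  expect_error(achievement_regression(d[d$trial_type == "standard", ],
                                      "effort"), "trial types")
})

test_that("behavioural rates use the stated denominators", {
  tr <- toy_trials()
  r <- behavioral_rates(tr)
  ps <- r$per_subject
  expect_equal(ps$precommit_rate, 1 / 3)
  expect_equal(ps$opt_out_rate, 1 / 2)          # 1 opt-out of 2 LR choices
  expect_equal(ps$opt_out_rate_trials, 1 / 3)   # of 3 standard trials
  expect_equal(ps$achieved_standard, 1 / 3)
  expect_equal(ps$achieved_precommitment, 2 / 3)
  expect_equal(ps$precommit_benefit, 1)
  # forced always-precommit agent
  tr2 <- tr
  tr2$precommit[tr2$trial_type == "precommitment"] <- "yes"
  tr2$choice[tr2$trial_type == "precommitment"] <- "LR"
  expect_equal(behavioral_rates(tr2)$per_subject$precommit_rate, 1)
  # opt-out rate against a count oracle: 1 opt-out in 200 standard trials
  n <- 200
  big <- data.frame(subject_id = "z", task = "effort",
                    trial_index = seq_len(n) - 1, trial_type = "standard",
                    cost_level = 2, precommit = NA_character_,
                    choice = "LR", opt_out = c(TRUE, rep(FALSE, n - 1)),
                    achieved_LR = c(FALSE, rep(TRUE, n - 1)))
  expect_equal(behavioral_rates(big)$per_subject$opt_out_rate_trials, 0.005)
  # zero denominators flagged as NA
  no_pre <- tr[tr$trial_type == "standard", ]
  expect_true(is.na(behavioral_rates(no_pre)$per_subject$precommit_rate))
})

test_that("cross-task correlations behave at the rank extremes", {
  x <- c(3, 1, 4, 1.5, 9)
  r1 <- cross_task_correlation(x, rank(x))
  expect_equal(r1$rho, 1)
  r2 <- cross_task_correlation(x, -x)
  expect_equal(r2$rho, -1)
  expect_warning(r3 <- cross_task_correlation(x, rep(1, 5)), "constant")
  expect_true(r3$degenerate)
  expect_error(cross_task_correlation(1:2, 1:2), "3 complete pairs")
})

test_that("a shared latent bias is detectable across tasks at n = 58", {
  # generative model of the cohort's b parameters: shared latent (sd 1)
  # plus task-specific jitter (sd 0.5), as in the default simulator
  set.seed(202)
  hits <- 0
  for (r in 1:150) {
    lat <- rnorm(58, 0, 1)
    b_eff <- -1.46 + lat + rnorm(58, 0, 0.5)
    b_del <- -1.10 + lat + rnorm(58, 0, 0.5)
    ct <- cross_task_correlation(b_eff, b_del)
    if (!is.na(ct$p) && ct$p < 0.05 && ct$rho > 0) hits <- hits + 1
  }
  expect_gte(hits / 150, 0.8)
})
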