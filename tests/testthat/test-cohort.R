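test_that("point-mass priors yield exactly those parameters", {
  pc <- point_prior_config("WP", discount = 0.3, gamma = 5, iota = 0.4,
                           theta = 2, b_mean = -1)
  sp <- draw_subject_params(pc, "effort", seed = 3)
  expect_equal(sp$discount, 0.3)
  expect_equal(sp$gamma, 5)
  expect_equal(sp$iota, 0.4)
  expect_equal(sp$theta, 2)
  expect_equal(sp$b, -1)
  sp_mm <- draw_subject_params(point_prior_config("MM"), "delay", seed = 3)
  expect_true(is.na(sp_mm$iota))
})

test_that("prior draws respect bounds and the truncated-normal mean", {
  pr <- default_prior_config()$effort$discount
  set.seed(99)
  draws <- draw_prior(pr, 1000)
  expect_true(all(draws >= 0 & draws <= 1))
  # analytic truncated-normal mean as the oracle
  m <- precom:::truncnorm_mean(pr$mean, pr$sd, pr$min, pr$max)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - m), 3 * se)
})

test_that("trial records satisfy their structural invariants", {
  for (s in 1:6) {
    gen <- if (s %% 2) "MM" else "WP"
    ch <- simulate_cohort(3, prior_config = default_prior_config(gen),
                          design_reps = 5, seed = s)
    expect_valid_records(ch$trials)
    # per subject/task counts match the design
    counts <- table(ch$trials$subject_id, ch$trials$task)
    expect_true(all(counts == 2 * 3 * 5))
  }
})

test_that("cohort simulation is deterministic and sized by the design", {
  ch1 <- simulate_cohort(1, seed = 5)
  ch2 <- simulate_cohort(1, seed = 5)
  expect_identical(ch1$trials, ch2$trials)
  expect_identical(ch1$subjects, ch2$subjects)
  expect_equal(nrow(ch1$trials), 120)  # 60 per task
  ch3 <- simulate_cohort(1, seed = 6)
  expect_false(identical(ch1$trials, ch3$trials))
  expect_error(simulate_cohort(0), "n_subjects")
})

test_that("simulated choice frequencies match the closed-form softmax", {
  sp <- point_spec(discount = 0.21, gamma = 4)
  design <- data.frame(task = "effort", trial_index = 0:9999,
                       trial_type = "standard",
                       cost_level = rep(c(2, 4, 6), length.out = 10000))
  set.seed(31)
  trials <- precom:::simulate_subject_task(sp, design)
  for (cost in c(2, 4, 6)) {
    p <- p_choice_lr(net_value_mm(7.5, 3.5, cost, 0.21), 4)
    n <- sum(design$cost_level == cost)
    obs <- sum(trials$choice[trials$cost_level == cost] == "LR")
    ci <- qbinom(c(0.005, 0.995), n, p)
    expect_gte(obs, ci[1])
    expect_lte(obs, ci[2])
  }
})

test_that("deterministic limits of the trial generator hold", {
  # enormous gamma, positive dV, no lapses: always LR and achieved
  sp <- point_spec(discount = 0.01, gamma = 100)
  d <- generate_task_design("effort", seed = 2)
  set.seed(8)
  tr <- precom:::simulate_subject_task(sp, d)
  free <- is.na(tr$precommit) | tr$precommit == "no"
  expect_true(all(tr$choice[free] == "LR"))
  expect_true(all(tr$achieved_LR[tr$precommit %in% "yes"]))
})

test_that("opt-out lapses occur at the configured rate", {
  # strong LR preference so nearly every standard trial is an LR choice
  pc <- point_prior_config(discount = 0.01, gamma = 20, opt_out = 0.05)
  ch <- simulate_cohort(40, tasks = "effort", prior_config = pc, seed = 12)
  std <- ch$trials[ch$trials$trial_type == "standard" &
                     ch$trials$choice == "LR", ]
  n <- nrow(std)
  obs <- sum(std$opt_out)
  ci <- qbinom(c(0.005, 0.995), n, 0.05)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("willpower suppression raises LR-choice probability", {
  # closed-form: for the same discount rate, iota < 1 inflates dV
  for (cost in c(2, 4, 6)) {
    p_mm <- p_choice_lr(net_value_mm(7.5, 3.5, cost, 0.3), 6)
    p_wp <- p_choice_lr(net_value_wp(7.5, 3.5, cost, 0.3, 0.4), 6)
    expect_gt(p_wp, p_mm)
  }
})

test_that("trial CSV round-trips losslessly", {
  ch <- simulate_cohort(2, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(ch$trials, path)
  back <- read_trials_csv(path)
  rownames(ch$trials) <- NULL
  expect_equal(back, ch$trials)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.csv",
                                               "true_parameters.csv",
                                               "provenance.json")))))
})
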