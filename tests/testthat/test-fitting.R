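test_that("fitting subsets follow the precommitment bookkeeping", {
  tr <- toy_trials()
  ch <- select_fit_data(tr, "MM_choice")
  expect_equal(nrow(ch), 5)  # 3 standard + 2 rejected precommitment
  expect_true(all(ch$trial_type == "standard" | ch$precommit == "no"))
  pre <- select_fit_data(tr, "MM_precom")
  expect_equal(nrow(pre), 3)
  # a subject who always precommits contributes only standard trials
  tr2 <- tr
  tr2$precommit[tr2$trial_type == "precommitment"] <- "yes"
  tr2$choice[tr2$trial_type == "precommitment"] <- "LR"
  expect_equal(nrow(select_fit_data(tr2, "WP_choice")), 3)
  # one who never precommits contributes everything
  tr3 <- tr
  tr3$precommit[tr3$trial_type == "precommitment"] <- "no"
  expect_equal(nrow(select_fit_data(tr3, "MM_choice")), 6)
  expect_error(select_fit_data(tr, "MM_choice", subject = "zz"),
               "insufficient")
})

test_that("negative log-likelihood matches a brute-force per-trial sum", {
  set.seed(21)
  sp <- point_spec(discount = 0.25, gamma = 3)
  design <- data.frame(task = "effort", trial_index = 0:9,
                       trial_type = "standard",
                       cost_level = rep(c(2, 4, 6), length.out = 10))
  tr <- precom:::simulate_subject_task(sp, design)
  rw <- list(M_LR = 7.5, M_SR = 3.5)
  params <- c(discount = 0.18, gamma = 2.4)
  # independent loop-summation oracle
  manual <- 0
  for (i in seq_len(nrow(tr))) {
    p <- 1 / (1 + exp(-params[["gamma"]] *
                        (rw$M_LR / (1 + params[["discount"]] *
                                      tr$cost_level[i]) - rw$M_SR)))
    manual <- manual - log(if (tr$choice[i] == "LR") p else 1 - p)
  }
  expect_lt(abs(negative_log_likelihood(params, tr, "MM_choice", "choice",
                                        rw) - manual), 1e-10)
  # chance-level parameters give n * ln 2
  expect_equal(negative_log_likelihood(c(discount = 0.4, gamma = 0), tr,
                                       "MM_choice", "choice", rw),
               10 * log(2))
  # precommitment model against the same oracle
  trp <- tr
  trp$trial_type <- "precommitment"
  trp$precommit <- ifelse(tr$choice == "LR", "yes", "no")
  trp$v_precom <- v_precom_mm(subjective_value(rw$M_LR, trp$cost_level, 0.25),
                              rw$M_SR)
  pp <- c(theta = 1.7, b = -0.6)
  manual_p <- -sum(ifelse(trp$precommit == "yes",
                          log(1 / (1 + exp(-(pp[["theta"]] * trp$v_precom +
                                               pp[["b"]])))),
                          log(1 - 1 / (1 + exp(-(pp[["theta"]] *
                                                   trp$v_precom + pp[["b"]]))))))
  expect_lt(abs(negative_log_likelihood(pp, trp, "MM_precom",
                                        "precommit_decision") - manual_p),
            1e-10)
})

test_that("maximum likelihood recovers generating parameters at 600 trials", {
  set.seed(5)
  tr <- precom:::simulate_choice_trials(600, list(M_LR = 7.5, M_SR = 3.5),
                                        discount = 0.2, gamma = 6)
  fit <- fit_subject(tr, "MM_choice", "choice",
                     list(M_LR = 7.5, M_SR = 3.5), n_starts = 10, seed = 2)
  expect_lt(abs(fit$estimates[["discount"]] - 0.2), 0.05)
  expect_true(fit$reliable)
  # dense-grid likelihood search as an independent cross-check
  grid <- expand.grid(discount = seq(0.05, 0.5, by = 0.005),
                      gamma = seq(1, 20, by = 0.25))
  nll <- mapply(function(k, g)
    negative_log_likelihood(c(discount = k, gamma = g), tr, "MM_choice",
                            "choice", list(M_LR = 7.5, M_SR = 3.5)),
    grid$discount, grid$gamma)
  expect_lte(-fit$logLik, min(nll) + 1e-6)
  best <- grid[which.min(nll), ]
  expect_lt(abs(fit$estimates[["discount"]] - best$discount), 0.01)
})

test_that("fits are deterministic given the seed", {
  set.seed(77)
  tr <- precom:::simulate_choice_trials(60, list(M_LR = 7.5, M_SR = 3.5),
                                        0.25, 5)
  f1 <- fit_subject(tr, "MM_choice", "choice", list(M_LR = 7.5, M_SR = 3.5),
                    n_starts = 8, seed = 4)
  f2 <- fit_subject(tr, "MM_choice", "choice", list(M_LR = 7.5, M_SR = 3.5),
                    n_starts = 8, seed = 4)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$logLik, f2$logLik)
})

test_that("pinning iota at 1 reproduces the MM fit exactly", {
  set.seed(13)
  tr <- precom:::simulate_choice_trials(90, list(M_LR = 7.5, M_SR = 3.5),
                                        0.3, 4)
  rw <- list(M_LR = 7.5, M_SR = 3.5)
  mm <- fit_subject(tr, "MM_choice", "choice", rw, n_starts = 10, seed = 6)
  wp1 <- fit_subject(tr, "WP_choice", "choice", rw, n_starts = 10, seed = 6,
                     bounds = list(discount = c(0, 1), gamma = c(0, 100),
                                   iota = c(1, 1)))
  expect_equal(wp1$logLik, mm$logLik, tolerance = 1e-8)
  expect_equal(wp1$n_params, 2)  # pinned parameter not counted
  expect_equal(wp1$bic, mm$bic, tolerance = 1e-6)
})

test_that("zero-variance choice data are flagged unreliable", {
  tr <- precom:::simulate_choice_trials(60, list(M_LR = 7.5, M_SR = 3.5),
                                        0.01, 100)  # all LR
  expect_true(all(tr$choice == "LR"))
  fit <- fit_subject(tr, "WP_choice", "choice", list(M_LR = 7.5, M_SR = 3.5),
                     n_starts = 6, seed = 1)
  expect_false(fit$reliable)
})

test_that("achievement fits mirror choice fits without opt-outs", {
  pc <- point_prior_config(discount = 0.3, gamma = 5, opt_out = 0)
  ch <- simulate_cohort(1, tasks = "effort", prior_config = pc, seed = 44)
  rw <- list(M_LR = ch$subjects$M_LR[1], M_SR = ch$subjects$M_SR[1])
  sub <- select_fit_data(ch$trials, "WP_choice")
  f_ch <- fit_subject(sub, "WP_choice", "choice", rw, n_starts = 8, seed = 2)
  f_re <- fit_wp_achievement(ch$trials, subject = ch$subjects$subject_id[1],
                             task = "effort", reward = rw, n_starts = 8,
                             seed = 2)
  # without lapses achievement == choice on the fitting subset
  expect_identical(sub$achieved_LR, sub$choice == "LR")
  expect_equal(f_re$logLik, f_ch$logLik)
  expect_equal(f_re$estimates, f_ch$estimates)
})

test_that("heavy opt-out lowers iota_reward relative to iota_choice", {
  pc <- point_prior_config("WP", discount = 0.25, gamma = 5, iota = 0.6,
                           opt_out = 0.3)
  diffs <- numeric(12)
  for (i in seq_len(12)) {
    ch <- simulate_cohort(1, tasks = "effort", prior_config = pc,
                          seed = 500 + i)
    rw <- list(M_LR = ch$subjects$M_LR[1], M_SR = ch$subjects$M_SR[1])
    sub <- select_fit_data(ch$trials, "WP_choice")
    f_ch <- fit_subject(sub, "WP_choice", "choice", rw, n_starts = 6, seed = 3)
    f_re <- fit_subject(sub, "WP_choice", "achievement", rw, n_starts = 6,
                        seed = 3)
    diffs[i] <- f_re$estimates[["iota"]] - f_ch$estimates[["iota"]]
  }
  expect_lt(mean(diffs), 0)
})

test_that("cohort fitting assembles all five fits per subject-task", {
  ch <- simulate_cohort(2, tasks = "effort", seed = 3)
  fits <- fit_cohort(ch, n_starts = 6, seed = 1)
  expect_equal(nrow(fits), 2 * 5)
  expect_setequal(unique(paste(fits$model, fits$outcome)),
                  c("MM_choice choice", "WP_choice choice",
                    "WP_choice achievement", "MM_precom precommit_decision",
                    "WP_precom precommit_decision"))
  expect_true(all(fits$logLik <= 0))
  expect_true(all(fits$pseudo_r2 >= 0 & fits$pseudo_r2 <= 1))
  expect_equal(fits$bic,
               fits$n_params * log(fits$n_trials) - 2 * fits$logLik)
})
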