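test_that("recovery studies are reproducible and structurally sound", {
  g <- data.frame(discount = 0.25, gamma = 8)
  r1 <- recovery_study("MM_choice", g, trials_per_subject = 60, n_reps = 2,
                       seed = 9, n_starts = 5)
  r2 <- recovery_study("MM_choice", g, trials_per_subject = 60, n_reps = 2,
                       seed = 9, n_starts = 5)
  expect_identical(r1$table, r2$table)
  expect_equal(nrow(r1$table), 2)
  # RMSE >= |bias| by construction
  expect_true(all(r1$by_parameter$rmse >= abs(r1$by_parameter$bias) - 1e-12))
  expect_error(recovery_study("MM_choice", g[0, ], n_reps = 1), "non-empty")
  expect_error(recovery_study("MM_choice", data.frame(discount = 2,
                                                      gamma = 5)),
               "outside fitting bounds")
})

test_that("precommitment-model parameters recover from decisions", {
  g <- expand.grid(theta = c(1, 4), b = c(-2, 0))
  r <- recovery_study("MM_precom", g, trials_per_subject = 300, n_reps = 4,
                      seed = 14, n_starts = 6)
  bp <- r$by_parameter
  expect_gt(bp$spearman_rho[bp$parameter == "theta"], 0.6)
  expect_gt(bp$spearman_rho[bp$parameter == "b"], 0.6)
  expect_lt(abs(bp$bias[bp$parameter == "b"]), 0.5)
})

test_that("more trials do not worsen discount recovery", {
  g <- data.frame(discount = 0.25, gamma = 8)
  r60 <- recovery_study("MM_choice", g, trials_per_subject = 60,
                        n_reps = 25, seed = 2, n_starts = 6)
  r600 <- recovery_study("MM_choice", g, trials_per_subject = 600,
                         n_reps = 25, seed = 2, n_starts = 6)
  rmse <- function(r) r$by_parameter$rmse[r$by_parameter$parameter ==
                                            "discount"]
  expect_lte(rmse(r600), rmse(r60) + 0.005)
})

test_that("deterministic choices pin the discount to the indifference region", {
  # gamma at bound: the agent chooses LR exactly when dV > 0; with true
  # discount 0.35 the pattern over costs (2,4,6) is (LR, SR, SR), which any
  # discount in the bracketing indifference interval reproduces
  tr <- precom:::simulate_choice_trials(60, list(M_LR = 7.5, M_SR = 3.5),
                                        discount = 0.35, gamma = 100)
  expect_true(all((tr$choice == "LR") == (tr$cost_level == 2)))
  fit <- fit_subject(tr, "MM_choice", "choice", list(M_LR = 7.5, M_SR = 3.5),
                     n_starts = 10, seed = 3)
  k_lo <- (7.5 / 3.5 - 1) / 4  # indifferent at cost 4
  k_hi <- (7.5 / 3.5 - 1) / 2  # indifferent at cost 2
  expect_gt(fit$estimates[["discount"]], k_lo)
  expect_lt(fit$estimates[["discount"]], k_hi)
})

test_that("iota is unidentifiable without discounting", {
  ic <- identifiability_check_iota(epsilons = c(0, 0.3),
                                   iotas = c(0.25, 0.5, 0.75),
                                   n_reps = 8, seed = 6, n_starts = 6)
  be <- ic$by_epsilon
  expect_equal(be$unreliable_fraction[be$discount == 0], 1)
  expect_gt(be$unreliable_fraction[be$discount == 0],
            be$unreliable_fraction[be$discount == 0.3])
})

test_that("degenerate choosers are flagged and only they are", {
  tr <- rbind(
    transform(toy_trials(), subject_id = "mixed"),
    transform(toy_trials(), subject_id = "allLR", choice = "LR",
              opt_out = FALSE, achieved_LR = TRUE,
              precommit = ifelse(trial_type == "precommitment", "no", NA)))
  flags <- flag_degenerate_subjects(tr)
  expect_equal(flags$subject_id, "allLR")
  expect_equal(flags$pattern, "all_LR")
  # an even split is not degenerate
  half <- transform(toy_trials(), subject_id = "half",
                    choice = c("LR", "SR", "LR", "LR", "SR", "LR"),
                    opt_out = FALSE,
                    achieved_LR = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(nrow(flag_degenerate_subjects(half)), 0)
})

test_that("model recovery study produces a labelled confusion table", {
  mr <- model_recovery_study(n_cohorts = 2, n_subjects = 6, seed = 4,
                             n_starts = 5)
  expect_equal(mr$generative, c("MM", "WP"))
  expect_true(all(mr$choice_winner %in% c("MM", "WP")))
  expect_true(all(mr$precom_winner %in% c("MM", "WP")))
  # MM-generated cohorts select the MM choice model
  expect_true(mr$choice_correct[1])
})
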