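# Shared fixtures, built in code.

# A deterministic agent spec with point parameters.
point_spec <- function(task = "effort", model = "MM", discount = 0.21,
                       gamma = 6.6, iota = NA_real_, theta = 3.7, b = -1.5,
                       opt_out = 0, M_LR = 7.5, M_SR = 3.5) {
  structure(list(subject_id = "t1", task = task, generative_model = model,
                 reward_set = structure(list(M_LR = M_LR, M_SR = M_SR,
                                             n_LR = 4, n_SR = 4),
                                        class = "reward_set"),
                 discount = discount, gamma = gamma, iota = iota,
                 theta = theta, b = b, opt_out_prob = opt_out,
                 achievement_failure_prob = 0),
            class = "subject_spec")
}

point_prior_config <- function(model = "MM", discount = 0.21, gamma = 6.6,
                               iota = 0.4, theta = 3.7, b_mean = -1.5,
                               opt_out = 0) {
  pc <- default_prior_config(model)
  for (tk in c("effort", "delay")) {
    pc[[tk]]$discount <- prior_point(discount)
    pc[[tk]]$gamma <- prior_point(gamma)
    pc[[tk]]$theta <- prior_point(theta)
    pc[[tk]]$b_mean <- b_mean
    pc[[tk]]$opt_out_prob <- opt_out
  }
  pc$iota <- prior_point(iota)
  pc$b_sd <- 0
  pc$b_task_sd <- 0
  pc
}

# Tiny hand-built trial table with known counts.
toy_trials <- function() {
  data.frame(
    subject_id = rep("a", 6),
    task = "effort",
    trial_index = 0:5,
    trial_type = c("standard", "standard", "standard",
                   "precommitment", "precommitment", "precommitment"),
    cost_level = c(2, 4, 6, 2, 4, 6),
    precommit = c(NA, NA, NA, "yes", "no", "no"),
    choice = c("LR", "SR", "LR", "LR", "LR", "SR"),
    opt_out = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    achieved_LR = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

expect_valid_records <- function(trials) {
  std <- trials$trial_type == "standard"
  expect_true(all(is.na(trials$precommit[std])))
  expect_true(all(!is.na(trials$precommit[!std])))
  yes <- !is.na(trials$precommit) & trials$precommit == "yes"
  expect_true(all(trials$choice[yes] == "LR"))
  expect_true(all(trials$choice[trials$opt_out] == "LR"))
  expect_true(all(!trials$achieved_LR[trials$opt_out]))
  ach <- trials$achieved_LR
  expect_true(all(trials$choice[ach] == "LR"))
  expect_true(all(!trials$opt_out[ach]))
}
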