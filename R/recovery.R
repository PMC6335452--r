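# Parameter- and model-recovery studies: simulate agents with known
# parameters, refit, and summarize how well truth is recovered — including
# the identifiability failure of the willpower parameter when a subject
# applies no discounting at all (its choices then carry no variance).

# Simulate standard-type choice trials for one agent (cost levels cycled,
# softmax choices); used by the recovery studies, where only the choice
# stage is under scrutiny.
simulate_choice_trials <- function(n_trials, reward, discount, gamma,
                                   iota = NA_real_, task = "effort") {
  costs <- rep_len(default_cost_levels(task), n_trials)
  sv_lr <- subjective_value(reward$M_LR, costs, discount)
  dv <- if (is.na(iota)) sv_lr - reward$M_SR else sv_lr - iota * reward$M_SR
  ch <- stats::rbinom(n_trials, 1, p_choice_lr(dv, gamma)) == 1
  data.frame(subject_id = "sim", task = task,
             trial_index = seq_len(n_trials) - 1L,
             trial_type = "standard", cost_level = costs,
             precommit = NA_character_,
             choice = ifelse(ch, "LR", "SR"), opt_out = FALSE,
             achieved_LR = ch, stringsAsFactors = FALSE)
}

# Simulate precommitment-type trials given per-trial precommitment values.
simulate_precom_trials <- function(v, theta, b, task = "effort") {
  n <- length(v)
  yes <- stats::rbinom(n, 1, p_precommit(v, theta, b)) == 1
  data.frame(subject_id = "sim", task = task,
             trial_index = seq_len(n) - 1L,
             trial_type = "precommitment",
             cost_level = rep_len(default_cost_levels(task), n),
             precommit = ifelse(yes, "yes", "no"),
             choice = ifelse(yes, "LR", "SR"), opt_out = FALSE,
             achieved_LR = yes, v_precom = v, stringsAsFactors = FALSE)
}

#' Parameter-recovery study
#'
#' For every row of `true_grid` and every replicate: simulate an agent with
#' those parameters, refit the same model by maximum likelihood, and record
#' true and recovered values. Summaries report bias, RMSE and the Spearman
#' correlation between true and recovered values per parameter (pooled over
#' the grid), and the unreliable-fit fraction per grid cell.
#'
#' Choice models are simulated on standard-type trials; precommitment
#' models on precommitment trials whose per-trial value is computed from
#' the fixed reward set and discount rate (as in the real pipeline, where
#' values enter the precommitment fit as fixed inputs).
#'
#' @param model Model name (see [default_bounds()]).
#' @param true_grid Data.frame of true parameters: `discount`, `gamma`
#'   (and `iota` for `WP_choice`), or `theta`, `b` for precommitment
#'   models.
#' @param trials_per_subject Trials simulated per replicate.
#' @param n_reps Replicates per grid row.
#' @param seed Integer seed.
#' @param n_starts Starts per fit.
#' @param task Task whose cost levels are used.
#' @param reward Reward magnitudes (list with `M_LR`, `M_SR`).
#' @param discount Discount rate used to build precommitment values (for
#'   precommitment models only).
#' @return A list of class `recovery_report`: `table` (one row per
#'   replicate), `by_parameter`, `by_cell`, `config`.
#' @export
recovery_study <- function(model, true_grid, trials_per_subject = 60,
                           n_reps = 10, seed = 1, n_starts = 10,
                           task = "effort",
                           reward = list(M_LR = 7.5, M_SR = 3.5),
                           discount = 0.21) {
  if (!nrow(true_grid) || n_reps < 1)
    stop_config("true_grid must be non-empty and n_reps >= 1")
  bounds <- default_bounds(model)
  pnames <- names(bounds)
  if (!all(pnames %in% names(true_grid)))
    stop_config("true_grid must contain columns: ",
                paste(pnames, collapse = ", "))
  for (p in pnames) {
    if (any(true_grid[[p]] < bounds[[p]][1] | true_grid[[p]] > bounds[[p]][2]))
      stop_config("true values of ", p, " outside fitting bounds")
  }
  is_choice <- model %in% c("MM_choice", "WP_choice")
  rows <- list(); k <- 0L
  for (g in seq_len(nrow(true_grid))) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      sseed <- derive_seed(seed, paste(model, g), r)
      tg <- true_grid[g, , drop = FALSE]
      if (is_choice) {
        trials <- with_seed(sseed, simulate_choice_trials(
          trials_per_subject, reward, tg$discount, tg$gamma,
          if (model == "WP_choice") tg$iota else NA_real_, task))
        fit <- fit_subject(trials, model, "choice", reward,
                           n_starts = n_starts,
                           seed = derive_seed(sseed, "fit"))
      } else {
        costs <- rep_len(default_cost_levels(task), trials_per_subject)
        v <- v_precom_mm(subjective_value(reward$M_LR, costs, discount),
                         reward$M_SR)
        if (model == "WP_precom") v <- -v
        trials <- with_seed(sseed,
                            simulate_precom_trials(v, tg$theta, tg$b, task))
        fit <- fit_subject(trials, model, "precommit_decision", NULL,
                           n_starts = n_starts,
                           seed = derive_seed(sseed, "fit"))
      }
      row <- data.frame(cell = g, rep = r, reliable = fit$reliable)
      for (p in pnames) {
        row[[paste0("true_", p)]] <- tg[[p]]
        row[[paste0("est_", p)]] <- fit$estimates[[p]]
      }
      rows[[k]] <- row
    }
  }
  table <- do.call(rbind, rows)
  by_parameter <- do.call(rbind, lapply(pnames, function(p) {
    err <- table[[paste0("est_", p)]] - table[[paste0("true_", p)]]
    tv <- table[[paste0("true_", p)]]
    rho <- if (length(unique(tv)) > 1)
      suppressWarnings(stats::cor(tv, table[[paste0("est_", p)]],
                                  method = "spearman")) else NA_real_
    data.frame(parameter = p, bias = mean(err), rmse = sqrt(mean(err^2)),
               spearman_rho = rho, stringsAsFactors = FALSE)
  }))
  by_cell <- do.call(rbind, lapply(seq_len(nrow(true_grid)), function(g) {
    sub <- table[table$cell == g, ]
    cell <- data.frame(cell = g, n_reps = nrow(sub),
                       unreliable_fraction = mean(!sub$reliable))
    for (p in pnames) {
      err <- sub[[paste0("est_", p)]] - sub[[paste0("true_", p)]]
      cell[[paste0("true_", p)]] <- sub[[paste0("true_", p)]][1]
      cell[[paste0("bias_", p)]] <- mean(err)
      cell[[paste0("rmse_", p)]] <- sqrt(mean(err^2))
    }
    cell
  }))
  out <- list(table = table, by_parameter = by_parameter, by_cell = by_cell,
              config = list(model = model, trials_per_subject =
                              trials_per_subject, n_reps = n_reps,
                            seed = seed, n_starts = n_starts, task = task,
                            reward = reward))
  class(out) <- "recovery_report"
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("parameter recovery: %s, %d trials/agent, %d replicates/cell\n",
              x$config$model, x$config$trials_per_subject, x$config$n_reps))
  print(x$by_parameter, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Identifiability of the willpower parameter across discounting regimes
#'
#' Simulates willpower-model agents at each discount rate in `epsilons`
#' (crossed with `iotas`), refits the WP choice model, and contrasts the
#' unreliable-fit fraction and the true-vs-recovered iota correlation
#' between cells. Agents with discount approximately 0 choose the LR on
#' essentially every trial (its value dominates even the unsuppressed SR),
#' so their choices carry no variance and iota cannot be estimated.
#'
#' @param epsilons Discount rates to probe (should include a value near 0
#'   and one of at least 0.2).
#' @param iotas True willpower values crossed with `epsilons`.
#' @param gamma True inverse temperature.
#' @param trials_per_subject,n_reps,seed,n_starts,reward,task As in
#'   [recovery_study()].
#' @return A list of class `iota_identifiability`: `by_epsilon`
#'   (unreliable fraction and iota rank correlation per discount cell) and
#'   the underlying `report`.
#' @export
identifiability_check_iota <- function(epsilons = c(0, 0.3),
                                       iotas = c(0.25, 0.5, 0.75),
                                       gamma = 6.6,
                                       trials_per_subject = 60, n_reps = 10,
                                       seed = 1, n_starts = 10,
                                       reward = list(M_LR = 7.5, M_SR = 3.5),
                                       task = "effort") {
  grid <- expand.grid(discount = epsilons, iota = iotas,
                      KEEP.OUT.ATTRS = FALSE)
  grid$gamma <- gamma
  rep_ <- recovery_study("WP_choice", grid, trials_per_subject, n_reps,
                         seed, n_starts, task, reward)
  tab <- rep_$table
  by_eps <- do.call(rbind, lapply(epsilons, function(e) {
    sub <- tab[abs(tab$true_discount - e) < 1e-12, ]
    rho <- if (length(unique(sub$true_iota)) > 1)
      suppressWarnings(stats::cor(sub$true_iota, sub$est_iota,
                                  method = "spearman")) else NA_real_
    data.frame(discount = e, n = nrow(sub),
               unreliable_fraction = mean(!sub$reliable),
               iota_spearman_rho = rho)
  }))
  structure(list(by_epsilon = by_eps, report = rep_),
            class = "iota_identifiability")
}

#' @export
print.iota_identifiability <- function(x, ...) {
  cat("willpower-parameter identifiability by discount rate:\n")
  print(x$by_epsilon, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Flag subjects with no variance in their choice data
#'
#' Subjects choosing the LR (or SR) on every trial of the choice-model
#' fitting subset are flagged; their willpower parameter is unidentifiable
#' and they can be excluded from choice-model comparisons as a robustness
#' check.
#'
#' @param trials Trial-record data.frame.
#' @return Data.frame with `subject_id`, `task`, `pattern` (`"all_LR"` or
#'   `"all_SR"`); zero rows when no subject is degenerate.
#' @export
flag_degenerate_subjects <- function(trials) {
  combos <- unique(trials[c("subject_id", "task")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- select_fit_data(trials, "MM_choice", combos$subject_id[i],
                           combos$task[i])
    lr <- sub$choice == "LR"
    if (all(lr) || all(!lr))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = combos$subject_id[i], task = combos$task[i],
        pattern = if (all(lr)) "all_LR" else "all_SR",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(subject_id = character(0), task = character(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Model-recovery study at cohort scale
#'
#' Simulates replicate cohorts alternately from the motivation-maximization
#' and willpower generative models, runs the full fitting pipeline on each,
#' and records which choice model and which precommitment model win the
#' group-BIC comparison, yielding a model-recovery confusion table.
#'
#' @param n_cohorts Number of replicate cohorts (alternating generative
#'   model).
#' @param n_subjects Subjects per cohort.
#' @param seed Integer seed.
#' @param n_starts Starts per fit.
#' @param task Task simulated (one task keeps the study at the 60-trials-
#'   per-subject regime).
#' @param iota_prior Prior for the willpower factor of WP cohorts.
#' @param wp_discount_prior Optional override of the discount prior for WP
#'   cohorts (the willpower regime is only identifiable when discounting is
#'   strong enough for the suppressed net value to change sign across cost
#'   levels).
#' @return Data.frame: one row per cohort with the generative model, both
#'   winners, and correctness indicators.
#' @export
model_recovery_study <- function(n_cohorts = 20, n_subjects = 58, seed = 1,
                                 n_starts = 10, task = "effort",
                                 iota_prior = prior_uniform(0.2, 0.5),
                                 wp_discount_prior = NULL) {
  rows <- vector("list", n_cohorts)
  for (c_i in seq_len(n_cohorts)) {
    gen <- if (c_i %% 2 == 1) "MM" else "WP"
    pc <- default_prior_config(gen)
    if (gen == "WP") {
      pc$iota <- iota_prior
      if (!is.null(wp_discount_prior)) pc[[task]]$discount <- wp_discount_prior
    }
    ch <- simulate_cohort(n_subjects, tasks = task, prior_config = pc,
                          seed = derive_seed(seed, "cohort", c_i))
    fits <- fit_cohort(ch, n_starts = n_starts,
                       seed = derive_seed(seed, "fits", c_i))
    choice_cmp <- compare_models(
      fits[fits$model == "MM_choice" & fits$outcome == "choice", ],
      fits[fits$model == "WP_choice" & fits$outcome == "choice", ])
    precom_cmp <- compare_models(
      fits[fits$model == "MM_precom", ], fits[fits$model == "WP_precom", ])
    rows[[c_i]] <- data.frame(
      cohort = c_i, generative = gen,
      choice_winner = sub("_choice", "", choice_cmp$winner),
      precom_winner = sub("_precom", "", precom_cmp$winner),
      choice_delta_bic = choice_cmp$group_delta_bic,
      precom_delta_bic = precom_cmp$group_delta_bic,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$choice_correct <- out$choice_winner == out$generative
  out$precom_correct <- out$precom_winner == out$generative
  out
}
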