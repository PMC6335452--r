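# Synthetic cohort generation: agents with known ("true") parameters acting
# on the two-task design, so that every downstream analysis stage can be
# exercised and validated without behavioural data.

# --- priors ------------------------------------------------------------

#' Prior (generative distribution) specification helpers
#'
#' A prior is a list with a `dist` field: `"point"` (a fixed `value`),
#' `"uniform"` (`min`, `max`) or `"normal"` (`mean`, `sd`, truncated to
#' `[min, max]` via the inverse-CDF method).
#'
#' @param value,mean,sd,min,max Distribution parameters.
#' @return A prior specification list.
#' @export
prior_point <- function(value) list(dist = "point", value = value)

#' @rdname prior_point
#' @export
prior_uniform <- function(min, max) {
  if (max < min) stop_config("prior_uniform: max < min")
  list(dist = "uniform", min = min, max = max)
}

#' @rdname prior_point
#' @export
prior_normal <- function(mean, sd, min = -Inf, max = Inf) {
  if (sd < 0 || max < min) stop_config("prior_normal: invalid parameters")
  list(dist = "normal", mean = mean, sd = sd, min = min, max = max)
}

#' Draw from a prior specification
#'
#' @param prior A prior list from [prior_point()], [prior_uniform()] or
#'   [prior_normal()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_prior <- function(prior, n = 1) {
  if (is.null(prior$dist)) stop_config("invalid prior specification")
  switch(prior$dist,
    point = rep(prior$value, n),
    uniform = stats::runif(n, prior$min, prior$max),
    normal = {
      lo <- stats::pnorm(prior$min, prior$mean, prior$sd)
      hi <- stats::pnorm(prior$max, prior$mean, prior$sd)
      stats::qnorm(stats::runif(n, lo, hi), prior$mean, prior$sd)
    },
    stop_config("unknown prior dist: ", prior$dist))
}

# Mean of a truncated normal; used by tests as an analytic oracle and by
# nothing else.
truncnorm_mean <- function(mean, sd, min, max) {
  a <- (min - mean) / sd; b <- (max - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Default generative configuration for a synthetic cohort
#'
#' Encodes the study conditions the simulator emulates: per-task discount
#' rates and inverse temperatures centred on the empirical group means of
#' the motivation-maximization choice model (effort: discount 0.21, gamma
#' 6.6; delay: discount 0.155, gamma 20.7), precommitment sensitivity and
#' bias centred on the winning precommitment model's group means, rare
#' opt-out lapses (0.5% of effort, 1.7% of delay standard-trial LR choices),
#' and a subject-level latent precommitment bias shared across tasks (which
#' induces the cross-task correlation of `b`).
#'
#' @param generative_model `"MM"` (motivation maximization) or `"WP"`
#'   (willpower suppression with factor iota).
#' @return A nested list of priors and rates used by [simulate_cohort()].
#' @export
default_prior_config <- function(generative_model = c("MM", "WP")) {
  generative_model <- match.arg(generative_model)
  list(
    generative_model = generative_model,
    effort = list(
      discount = prior_normal(0.21, 0.15, 0, 1),
      gamma    = prior_normal(6.6, 3, 0.5, 30),
      theta    = prior_normal(3.7, 1.5, 0.5, 10),
      b_mean   = -1.46,
      opt_out_prob = 0.005
    ),
    delay = list(
      discount = prior_normal(0.155, 0.15, 0, 1),
      gamma    = prior_normal(20.7, 8, 1, 67),
      theta    = prior_normal(5.7, 2, 0.5, 12),
      b_mean   = -1.10,
      opt_out_prob = 0.017
    ),
    iota = prior_uniform(0.2, 0.8),
    b_sd = 1.0,          # between-subject sd of the shared latent bias
    b_task_sd = 0.5,     # task-specific jitter around the latent bias
    achievement_failure_prob = 0,
    ratings = list(n_items = 100, mean = 5.5, sd = 2.5)
  )
}

# --- subject-level generative specs ------------------------------------

#' Draw one subject's generative parameters for one task
#'
#' @param prior_config Configuration from [default_prior_config()].
#' @param task `"effort"` or `"delay"`.
#' @param seed Integer seed.
#' @param subject_id Identifier stored in the spec.
#' @param reward_set Optional pre-built [build_reward_set()] result (the
#'   image set is shared across the two tasks); drawn from the ratings model
#'   if `NULL`.
#' @param b_latent Optional shared latent precommitment bias; drawn if `NULL`.
#' @return A list of class `subject_spec`.
#' @export
draw_subject_params <- function(prior_config, task = c("effort", "delay"),
                                seed = 1, subject_id = "s1",
                                reward_set = NULL, b_latent = NULL) {
  task <- match.arg(task)
  pc <- prior_config
  tk <- pc[[task]]
  if (is.null(tk)) stop_config("prior_config lacks settings for task ", task)
  with_seed(seed, {
    if (is.null(reward_set)) reward_set <- draw_reward_set(pc$ratings)
    if (is.null(b_latent)) b_latent <- stats::rnorm(1, 0, pc$b_sd %||% 1)
    discount <- draw_prior(tk$discount)
    gamma <- draw_prior(tk$gamma)
    iota <- if (pc$generative_model == "WP") draw_prior(pc$iota) else NA_real_
    theta <- draw_prior(tk$theta)
    b <- tk$b_mean + b_latent + stats::rnorm(1, 0, pc$b_task_sd %||% 0)
    b <- min(5, max(-5, b))
    check_prob(tk$opt_out_prob, "opt_out_prob")
    check_prob(pc$achievement_failure_prob %||% 0, "achievement_failure_prob")
    spec <- list(subject_id = subject_id, task = task,
                 generative_model = pc$generative_model,
                 reward_set = reward_set,
                 discount = discount, gamma = gamma, iota = iota,
                 theta = theta, b = b,
                 opt_out_prob = tk$opt_out_prob,
                 achievement_failure_prob = pc$achievement_failure_prob %||% 0)
    class(spec) <- "subject_spec"
    spec
  })
}

# Ratings model: integer 0-10 ratings from a rounded clamped normal; feeds
# build_reward_set() so simulated magnitudes inherit its exact semantics.
draw_reward_set <- function(ratings_cfg) {
  n <- ratings_cfg$n_items %||% 100
  r <- round(stats::rnorm(n, ratings_cfg$mean %||% 5.5, ratings_cfg$sd %||% 2.5))
  r <- pmin(10, pmax(0, r))
  build_reward_set(r)
}

# --- trial simulation --------------------------------------------------

# Vectorized simulation of one subject on one task design. Uses the
# generative model named in the spec for both choice and precommitment
# stages. RNG is taken from the current stream (callers seed it).
simulate_subject_task <- function(spec, design) {
  stopifnot(inherits(spec, "subject_spec"))
  n <- nrow(design)
  M_LR <- spec$reward_set$M_LR; M_SR <- spec$reward_set$M_SR
  sv_lr <- subjective_value(M_LR, design$cost_level, spec$discount)
  if (spec$generative_model == "MM") {
    dv <- sv_lr - M_SR
    v <- v_precom_mm(sv_lr, M_SR)
  } else {
    if (is.na(spec$iota))
      stop_config("WP generative model requires iota in the subject spec")
    dv <- sv_lr - spec$iota * M_SR
    v <- v_precom_wp(sv_lr, M_SR, spec$iota)
  }
  is_pre <- design$trial_type == "precommitment"
  precommit <- rep(NA_character_, n)
  pre_yes <- rep(FALSE, n)
  if (any(is_pre)) {
    p_pre <- p_precommit(v[is_pre], spec$theta, spec$b)
    pre_yes[is_pre] <- stats::rbinom(sum(is_pre), 1, p_pre) == 1
    precommit[is_pre] <- ifelse(pre_yes[is_pre], "yes", "no")
  }
  # free choice on standard trials and rejected-precommitment trials
  free <- !pre_yes
  choice <- rep("LR", n)
  p_lr <- p_choice_lr(dv, spec$gamma)
  choice[free] <- ifelse(stats::rbinom(sum(free), 1, p_lr[free]) == 1, "LR", "SR")
  lr <- choice == "LR"
  opt_out <- rep(FALSE, n)
  free_lr <- lr & free
  if (any(free_lr))
    opt_out[free_lr] <- stats::rbinom(sum(free_lr), 1, spec$opt_out_prob) == 1
  achieved <- lr & !opt_out
  if (spec$achievement_failure_prob > 0 && any(achieved))
    achieved[achieved] <- stats::rbinom(sum(achieved), 1,
                                        1 - spec$achievement_failure_prob) == 1
  data.frame(subject_id = spec$subject_id,
             task = design$task,
             trial_index = design$trial_index,
             trial_type = design$trial_type,
             cost_level = design$cost_level,
             precommit = precommit,
             choice = choice,
             opt_out = opt_out,
             achieved_LR = achieved,
             stringsAsFactors = FALSE)
}

#' Simulate a single trial
#'
#' Runs the generative process for one trial: on precommitment trials the
#' agent first accepts or rejects precommitment (Bernoulli with probability
#' [p_precommit()] of the model-specific precommitment value); if it
#' precommits, the SR is removed and the LR is pursued directly. Otherwise a
#' softmax choice is made; LR choices can be abandoned with the lapse
#' probability `opt_out_prob`, and an achieved LR can still fail with
#' `achievement_failure_prob`.
#'
#' @param spec A `subject_spec` from [draw_subject_params()].
#' @param trial One-row data.frame with `task`, `trial_index`, `trial_type`,
#'   `cost_level` (e.g. a row of [generate_task_design()]).
#' @param seed Optional seed.
#' @return One-row data.frame (a trial record).
#' @export
simulate_trial <- function(spec, trial, seed = NULL) {
  stopifnot(nrow(trial) == 1L)
  with_seed(seed, simulate_subject_task(spec, trial))
}

#' Simulate a full synthetic cohort
#'
#' Draws `n_subjects` agents from the prior configuration and simulates each
#' on a per-subject randomized design of every requested task. One reward
#' set and one latent precommitment bias are drawn per subject and shared
#' across tasks.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param tasks Character vector among `"effort"`, `"delay"`.
#' @param prior_config See [default_prior_config()].
#' @param design_reps Repetitions per (trial type, cost level) cell; 10
#'   reproduces the 60-trial session.
#' @param seed Integer seed; the cohort is a deterministic function of
#'   (configuration, seed).
#' @return A list of class `cohort`: `trials` (trial records), `subjects`
#'   (true generative parameters, one row per subject x task), `config`.
#' @examples
#' ch <- simulate_cohort(2, seed = 1)
#' nrow(ch$trials)  # 2 subjects x 2 tasks x 60 trials
#' @export
simulate_cohort <- function(n_subjects, tasks = c("effort", "delay"),
                            prior_config = default_prior_config(),
                            design_reps = 10, seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop_config("n_subjects must be >= 1")
  tasks <- match.arg(tasks, c("effort", "delay"), several.ok = TRUE)
  n_subjects <- as.integer(n_subjects)
  trials <- vector("list", n_subjects * length(tasks))
  subjects <- vector("list", n_subjects * length(tasks))
  k <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("s%03d", i)
    sseed <- derive_seed(seed, "subject", i)
    shared <- with_seed(sseed, list(
      reward_set = draw_reward_set(prior_config$ratings),
      b_latent = stats::rnorm(1, 0, prior_config$b_sd %||% 1)))
    for (task in tasks) {
      k <- k + 1L
      tseed <- derive_seed(sseed, task, 1L)
      spec <- draw_subject_params(prior_config, task, seed = tseed,
                                  subject_id = sid,
                                  reward_set = shared$reward_set,
                                  b_latent = shared$b_latent)
      design <- generate_task_design(task, reps = design_reps,
                                     seed = derive_seed(tseed, "design"))
      trials[[k]] <- with_seed(derive_seed(tseed, "behaviour"),
                               simulate_subject_task(spec, design))
      subjects[[k]] <- data.frame(
        subject_id = sid, task = task,
        generative_model = spec$generative_model,
        M_LR = spec$reward_set$M_LR, M_SR = spec$reward_set$M_SR,
        discount = spec$discount, gamma = spec$gamma, iota = spec$iota,
        theta = spec$theta, b = spec$b,
        opt_out_prob = spec$opt_out_prob,
        achievement_failure_prob = spec$achievement_failure_prob,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(trials = do.call(rbind, trials),
              subjects = do.call(rbind, subjects),
              config = list(n_subjects = n_subjects, tasks = tasks,
                            prior_config = prior_config,
                            design_reps = design_reps, seed = seed))
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects, tasks: %s, %d trial records\n",
              x$config$n_subjects, paste(x$config$tasks, collapse = ", "),
              nrow(x$trials)))
  invisible(x)
}

#' Simulate achievement data with no trial-type effect
#'
#' Null-model generator used for calibration of the repeated-measures
#' regression: each subject gets a random intercept (inducing within-subject
#' correlation) and fixed cost-level effects, and `achieved_LR` is drawn
#' identically for standard and precommitment trials, so any detected
#' Trial-Type effect is a false positive.
#'
#' @param n_subjects Number of subjects.
#' @param task Task label for the records.
#' @param reps Repetitions per (trial type, cost level) cell.
#' @param mu0 Baseline log-odds of achievement at the middle cost level.
#' @param cost_effects Log-odds offsets per cost level (low to high).
#' @param subject_sd SD of the subject random intercept.
#' @param seed Integer seed.
#' @return Trial-record data.frame (choice/opt-out fields filled neutrally).
#' @export
simulate_null_achievement <- function(n_subjects, task = "effort", reps = 4,
                                      mu0 = 1.0,
                                      cost_effects = c(0.8, 0, -0.8),
                                      subject_sd = 0.8, seed = 1) {
  levels <- default_cost_levels(task)
  if (length(cost_effects) != length(levels))
    stop_config("cost_effects must match the number of cost levels")
  with_seed(seed, {
    out <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      design <- generate_task_design(task, reps = reps,
                                     seed = stats::runif(1, 1, 2^30))
      u <- stats::rnorm(1, 0, subject_sd)
      eta <- mu0 + u + cost_effects[match(design$cost_level, levels)]
      ach <- stats::rbinom(nrow(design), 1, stats::plogis(eta)) == 1
      out[[i]] <- data.frame(
        subject_id = sprintf("s%03d", i), task = task,
        trial_index = design$trial_index, trial_type = design$trial_type,
        cost_level = design$cost_level,
        precommit = ifelse(design$trial_type == "precommitment", "no",
                           NA_character_),
        choice = ifelse(ach, "LR", "SR"), opt_out = FALSE,
        achieved_LR = ach, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# --- CSV / JSON I/O ----------------------------------------------------

#' Write and read trial-level data as CSV
#'
#' Schema: `subject_id, task, trial_index, trial_type, cost_level,
#' precommit, choice, opt_out, achieved_LR`; the `precommit` field is empty
#' on standard trials.
#'
#' @param trials Trial-record data.frame.
#' @param path File path.
#' @return `read_trials_csv` returns the trial-record data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  cols <- c("subject_id", "task", "trial_index", "trial_type", "cost_level",
            "precommit", "choice", "opt_out", "achieved_LR")
  missing <- setdiff(cols, names(trials))
  if (length(missing))
    stop_config("trials lack columns: ", paste(missing, collapse = ", "))
  utils::write.csv(trials[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      precommit = "character",
                                      choice = "character"))
  d$precommit[!is.na(d$precommit) & d$precommit == ""] <- NA_character_
  d$opt_out <- as.logical(d$opt_out)
  d$achieved_LR <- as.logical(d$achieved_LR)
  d
}

#' Write a cohort (trials, true parameters, config) to a directory
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials_csv(cohort$trials, file.path(dir, "trials.csv"))
  utils::write.csv(cohort$subjects, file.path(dir, "true_parameters.csv"),
                   row.names = FALSE, na = "")
  cfg <- cohort$config
  jsonlite::write_json(cfg[c("n_subjects", "tasks", "design_reps", "seed")],
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
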