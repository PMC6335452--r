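# Per-subject maximum-likelihood estimation with bounded multi-start
# optimization (L-BFGS-B), on the data subsets each model is defined over:
# choice models see standard trials plus precommitment trials in which the
# subject rejected precommitment; precommitment models see all
# precommitment trials and predict the accept/reject decision.

#' Default parameter bounds per model
#'
#' Choice models: discount rate in `[0, 1]`, inverse temperature gamma in
#' `[0, 100]`, willpower iota in `[0, 1]` (WP only). Precommitment models:
#' sensitivity theta in `[0, 100]`, bias b in `[-5, 5]`.
#'
#' @param model One of `"MM_choice"`, `"WP_choice"`, `"MM_precom"`,
#'   `"WP_precom"`.
#' @return Named list of `c(lower, upper)` pairs, in parameter order.
#' @export
default_bounds <- function(model) {
  switch(model,
    MM_choice = list(discount = c(0, 1), gamma = c(0, 100)),
    WP_choice = list(discount = c(0, 1), gamma = c(0, 100), iota = c(0, 1)),
    MM_precom = list(theta = c(0, 100), b = c(-5, 5)),
    WP_precom = list(theta = c(0, 100), b = c(-5, 5)),
    stop_config("unknown model: ", model))
}

#' Select the trials a model is fitted to
#'
#' Choice models: standard trials plus precommitment trials in which
#' precommitment was rejected. Precommitment models: all precommitment
#' trials (the fitted outcome is the accept/reject decision).
#'
#' @param trials Trial-record data.frame.
#' @param model Model name (see [default_bounds()]).
#' @param subject,task Optional filters applied first.
#' @return Subset of `trials`.
#' @export
select_fit_data <- function(trials, model, subject = NULL, task = NULL) {
  d <- trials
  if (!is.null(subject)) d <- d[d$subject_id %in% subject, , drop = FALSE]
  if (!is.null(task)) d <- d[d$task %in% task, , drop = FALSE]
  if (!nrow(d)) stop_config("insufficient data: no trials after filtering")
  if (model %in% c("MM_choice", "WP_choice")) {
    keep <- d$trial_type == "standard" |
      (d$trial_type == "precommitment" & !is.na(d$precommit) &
         d$precommit == "no")
  } else {
    keep <- d$trial_type == "precommitment"
  }
  out <- d[keep, , drop = FALSE]
  if (!nrow(out)) stop_config("insufficient data: empty fitting subset")
  out
}

# Outcome event vector for a fitting subset.
fit_event <- function(trials, outcome) {
  switch(outcome,
    choice = trials$choice == "LR",
    achievement = trials$achieved_LR,
    precommit_decision = {
      if (any(is.na(trials$precommit)))
        stop_config("precommit_decision outcome requires precommitment trials only")
      trials$precommit == "yes"
    },
    stop_config("unknown outcome: ", outcome))
}

#' Negative log-likelihood of a model on a fitting subset
#'
#' Bernoulli likelihood with per-trial event probabilities from the
#' valuation rules. The log-probabilities are evaluated directly on the
#' logit scale (`plogis(log.p = TRUE)`), so the objective is finite and
#' smooth for every bounded parameter value, including corners where the
#' predicted probability underflows. For precommitment models the
#' per-trial precommitment value must be supplied in a `v_precom` column
#' (it is fixed from prior choice-model fits, never re-estimated).
#'
#' @param params Named numeric vector (`discount`, `gamma`, optionally
#'   `iota`; or `theta`, `b`).
#' @param trials Fitting subset (see [select_fit_data()]).
#' @param model Model name.
#' @param outcome `"choice"`, `"achievement"` or `"precommit_decision"`.
#' @param reward A `reward_set` (or list with `M_LR`, `M_SR`); required for
#'   choice models.
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, trials, model,
                                    outcome = c("choice", "achievement",
                                                "precommit_decision"),
                                    reward = NULL) {
  outcome <- match.arg(outcome)
  if (any(is.na(params))) stop_config("NaN/NA parameter values")
  event <- fit_event(trials, outcome)
  x <- event_logit(params, trials, model, reward)
  -sum(stats::plogis(ifelse(event, x, -x), log.p = TRUE))
}

# Linear predictor (logit of the event probability) per trial.
event_logit <- function(params, trials, model, reward = NULL) {
  if (model %in% c("MM_choice", "WP_choice")) {
    if (is.null(reward)) stop_config("choice models require a reward set")
    dv <- if (model == "MM_choice")
      net_value_mm(reward$M_LR, reward$M_SR, trials$cost_level,
                   params[["discount"]])
    else
      net_value_wp(reward$M_LR, reward$M_SR, trials$cost_level,
                   params[["discount"]], params[["iota"]])
    if (params[["gamma"]] < 0) stop_config("gamma must be non-negative")
    params[["gamma"]] * dv
  } else {
    if (is.null(trials$v_precom))
      stop_config("precommitment models require a v_precom column")
    if (params[["theta"]] < 0) stop_config("theta must be non-negative")
    params[["theta"]] * trials$v_precom + params[["b"]]
  }
}

event_probability <- function(params, trials, model, reward = NULL) {
  stats::plogis(event_logit(params, trials, model, reward))
}

#' Fit one model to one subject's trials by maximum likelihood
#'
#' Bounded multi-start optimization: `n_starts` L-BFGS-B runs from seeded
#' uniform starting points within the bounds. Ties in the objective are
#' broken by the lexicographically smallest parameter vector, making the
#' result deterministic given the seed. The fit is flagged unreliable when
#' the second-best start's log-likelihood differs from the best by more
#' than 1e-3 (the starts disagree) or when the outcome has no variance.
#'
#' @param trials Fitting subset (already filtered via [select_fit_data()]).
#' @param model Model name.
#' @param outcome Outcome fitted (see [negative_log_likelihood()]).
#' @param reward Reward set for choice models.
#' @param n_starts Number of random starts (default 20).
#' @param seed Integer seed for the starts.
#' @param bounds Named list of `c(lower, upper)`; a parameter with equal
#'   bounds is held fixed at that value (e.g. pin `iota = c(1, 1)` to
#'   recover the MM fit from the WP model).
#' @param subject_id,task Labels carried into the result.
#' @return A list of class `fit_result`: `estimates`, `logLik`, `n_trials`,
#'   `bic`, `pseudo_r2`, `percent_correct`, `reliable`,
#'   `n_starts_agreeing`, plus the labels.
#' @export
fit_subject <- function(trials, model,
                        outcome = c("choice", "achievement",
                                    "precommit_decision"),
                        reward = NULL, n_starts = 20, seed = 1,
                        bounds = default_bounds(model),
                        subject_id = NA_character_, task = NA_character_) {
  outcome <- match.arg(outcome)
  if (!nrow(trials)) stop_config("insufficient data: empty fitting subset")
  pnames <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  if (any(upper < lower)) stop_config("invalid bounds")
  fixed <- upper == lower
  event <- fit_event(trials, outcome)

  # Collapse trials to unique covariate values (3 cost levels or a few
  # precommitment values) with event/non-event counts; the weighted
  # likelihood is identical to the per-trial sum but much cheaper.
  is_choice <- model %in% c("MM_choice", "WP_choice")
  cov <- if (is_choice) trials$cost_level else trials$v_precom
  u <- sort(unique(cov))
  w1 <- vapply(u, function(v) sum(event[cov == v]), numeric(1))
  w0 <- vapply(u, function(v) sum(!event[cov == v]), numeric(1))
  mini <- if (is_choice) data.frame(cost_level = u)
          else data.frame(v_precom = u)

  obj <- function(free) {
    full <- numeric(length(pnames)); names(full) <- pnames
    full[fixed] <- lower[fixed]; full[!fixed] <- free
    x <- event_logit(full, mini, model, reward)
    -(sum(w1 * stats::plogis(x, log.p = TRUE)) +
        sum(w0 * stats::plogis(-x, log.p = TRUE)))
  }

  nfree <- sum(!fixed)
  starts <- with_seed(seed, matrix(stats::runif(n_starts * nfree,
                                                rep(lower[!fixed], each = n_starts),
                                                rep(upper[!fixed], each = n_starts)),
                                   nrow = n_starts))
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      if (nfree == 0) list(par = numeric(0), value = obj(numeric(0)))
      else stats::optim(starts[s, ], obj, method = "L-BFGS-B",
                        lower = lower[!fixed], upper = upper[!fixed],
                        control = list(factr = 1e-8 / .Machine$double.eps,
                                       maxit = 500)),
      error = function(e) NULL)
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop_config("fit failure: all optimization starts failed for model ", model)
  vals <- vapply(fits[ok], `[[`, numeric(1), "value")
  pars <- lapply(fits[ok], `[[`, "par")
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-9)
  # deterministic tie-break: lexicographically smallest parameter vector
  if (length(cand) > 1) {
    ord <- do.call(order, as.data.frame(do.call(rbind, pars[cand])))
    cand <- cand[ord[1]]
  }
  best <- cand[1]
  est <- numeric(length(pnames)); names(est) <- pnames
  est[fixed] <- lower[fixed]; est[!fixed] <- pars[[best]]
  n_agree <- sum(vals <= best_val + 1e-3)
  varies <- length(unique(event)) > 1
  logLik <- -vals[best]
  n <- nrow(trials)
  k <- sum(!fixed)
  p_hat <- event_probability(est, trials, model, reward)
  correct <- ifelse(p_hat == 0.5, 0.5, (p_hat > 0.5) == event)
  out <- list(subject_id = subject_id, task = task, model = model,
              outcome = outcome, estimates = est, logLik = logLik,
              n_trials = n, n_params = k,
              bic = bic(logLik, k, n),
              pseudo_r2 = mcfadden_r2(logLik, n),
              percent_correct = mean(correct),
              reliable = (n_starts < 2 || n_agree >= 2) && varies,
              n_starts_agreeing = n_agree)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit (%s outcome), %d trials: logLik %.3f, BIC %.2f, pseudoR2 %.3f%s\n",
              x$model, x$outcome, x$n_trials, x$logLik, x$bic, x$pseudo_r2,
              if (x$reliable) "" else " [unreliable]"))
  print(round(x$estimates, 4))
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, ...) {
  est <- as.list(x$estimates)
  base <- data.frame(subject_id = x$subject_id, task = x$task,
                     model = x$model, outcome = x$outcome,
                     n_trials = x$n_trials, n_params = x$n_params,
                     logLik = x$logLik,
                     bic = x$bic, pseudo_r2 = x$pseudo_r2,
                     percent_correct = x$percent_correct,
                     reliable = x$reliable,
                     n_starts_agreeing = x$n_starts_agreeing,
                     stringsAsFactors = FALSE)
  for (p in c("discount", "gamma", "iota", "theta", "b"))
    base[[p]] <- est[[p]] %||% NA_real_
  base
}

#' Fit the WP choice model to achieved rewards
#'
#' Same subset as the choice fits (standard plus rejected-precommitment
#' trials) but with `achieved_LR` as the outcome; the resulting willpower
#' estimate is `iota_reward`, to contrast with `iota_choice` from the
#' choice-outcome fit.
#'
#' @inheritParams fit_subject
#' @param trials Full trial-record data.frame (subset selected internally).
#' @param subject,task Filters passed to [select_fit_data()].
#' @return A `fit_result`.
#' @export
fit_wp_achievement <- function(trials, subject = NULL, task = NULL,
                               reward = NULL, n_starts = 20, seed = 1) {
  sub <- select_fit_data(trials, "WP_choice", subject, task)
  fit_subject(sub, "WP_choice", outcome = "achievement", reward = reward,
              n_starts = n_starts, seed = seed,
              subject_id = subject %||% NA_character_,
              task = task %||% NA_character_)
}

#' Fit all models to every subject and task of a dataset
#'
#' Runs, per subject and task: the MM and WP choice models on choices, the
#' WP choice model on achieved rewards (yielding `iota_reward`), and the MM
#' and WP precommitment models on precommitment decisions. Precommitment
#' values are computed from the respective prior fits (MM: subjective
#' values from the MM choice fit; WP: `iota_reward` and subjective values
#' from the achievement fit) and held fixed.
#'
#' @param data A `cohort` object, or a trial-record data.frame (then
#'   `rewards` is required).
#' @param rewards Data.frame with `subject_id`, `M_LR`, `M_SR`; taken from
#'   the cohort's true parameters when `data` is a `cohort`.
#' @param n_starts,seed Passed to [fit_subject()].
#' @return Data.frame of class `cohort_fits`, one row per subject x task x
#'   (model, outcome).
#' @export
fit_cohort <- function(data, rewards = NULL, n_starts = 20, seed = 1) {
  if (inherits(data, "cohort")) {
    trials <- data$trials
    if (is.null(rewards))
      rewards <- unique(data$subjects[c("subject_id", "M_LR", "M_SR")])
  } else trials <- data
  if (is.null(rewards))
    stop_config("rewards (subject_id, M_LR, M_SR) are required")
  rows <- list()
  combos <- unique(trials[c("subject_id", "task")])
  combos <- combos[order(combos$subject_id, combos$task), ]
  for (i in seq_len(nrow(combos))) {
    sid <- combos$subject_id[i]; task <- combos$task[i]
    rw <- rewards[rewards$subject_id == sid, ]
    if (!nrow(rw)) stop_config("no reward set for subject ", sid)
    rw <- list(M_LR = rw$M_LR[1], M_SR = rw$M_SR[1])
    fseed <- derive_seed(seed, paste(sid, task), i)
    ch_sub <- select_fit_data(trials, "MM_choice", sid, task)
    mm <- fit_subject(ch_sub, "MM_choice", "choice", rw, n_starts,
                      derive_seed(fseed, "mm"), subject_id = sid, task = task)
    wp <- fit_subject(ch_sub, "WP_choice", "choice", rw, n_starts,
                      derive_seed(fseed, "wp"), subject_id = sid, task = task)
    wpa <- fit_subject(ch_sub, "WP_choice", "achievement", rw, n_starts,
                       derive_seed(fseed, "wpa"), subject_id = sid, task = task)
    pre_sub <- select_fit_data(trials, "MM_precom", sid, task)
    sv_sr <- rw$M_SR
    sv_lr_mm <- subjective_value(rw$M_LR, pre_sub$cost_level,
                                 mm$estimates[["discount"]])
    sv_lr_wpa <- subjective_value(rw$M_LR, pre_sub$cost_level,
                                  wpa$estimates[["discount"]])
    pre_mm <- pre_sub; pre_mm$v_precom <- v_precom_mm(sv_lr_mm, sv_sr)
    pre_wp <- pre_sub
    pre_wp$v_precom <- v_precom_wp(sv_lr_wpa, sv_sr, wpa$estimates[["iota"]])
    pm <- fit_subject(pre_mm, "MM_precom", "precommit_decision", NULL,
                      n_starts, derive_seed(fseed, "pm"),
                      subject_id = sid, task = task)
    pw <- fit_subject(pre_wp, "WP_precom", "precommit_decision", NULL,
                      n_starts, derive_seed(fseed, "pw"),
                      subject_id = sid, task = task)
    rows[[i]] <- do.call(rbind, lapply(list(mm, wp, wpa, pm, pw),
                                       as.data.frame))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_fits", class(out))
  out
}
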