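# Model-free analyses: the repeated-measures logistic regression of LR
# achievement, empirical behavioural rates, and cross-task rank
# correlations.

#' Repeated-measures logistic regression of LR achievement
#'
#' Fits GEE logistic regressions of the binary achievement outcome on the
#' categorical predictors Trial Type (standard vs precommitment) and
#' cost level (effort/waiting requirement of the LR), with subject as the
#' cluster. Candidate working correlations are scored by QIC and the
#' minimum-QIC fit is reported, together with robust Wald chi-square tests
#' per predictor and predicted achievement probabilities per condition
#' cell.
#'
#' @param trials Trial-record data.frame.
#' @param task Task to analyse (`"effort"` or `"delay"`).
#' @param candidates Working correlations to score.
#' @param interaction If `TRUE`, adds the Trial Type x cost interaction.
#' @return A list of class `achievement_regression`: `task`, `qic` (named,
#'   per candidate), `working_correlation` (selected), `fit`, `wald`,
#'   `cells` (predicted probability and s.e. per trial type x cost level),
#'   `interaction`.
#' @export
achievement_regression <- function(trials, task,
                                   candidates = c("independence",
                                                  "exchangeable"),
                                   interaction = FALSE) {
  d <- trials[trials$task == task, ]
  if (!nrow(d)) stop_config("no trials for task ", task)
  if (length(unique(d$subject_id)) < 2)
    stop_config("degenerate clustering: need at least 2 subjects")
  if (length(unique(d$trial_type)) < 2)
    stop_config("both trial types are required")
  d$achieved <- as.numeric(d$achieved_LR)
  d$trial_type <- factor(d$trial_type, levels = c("standard",
                                                  "precommitment"))
  d$cost <- factor(d$cost_level)
  fml <- if (interaction) achieved ~ trial_type * cost
         else achieved ~ trial_type + cost
  fits <- lapply(candidates, function(cs)
    gee_logit(fml, d, id = d$subject_id, corstr = cs))
  qic <- stats::setNames(vapply(fits, `[[`, numeric(1), "qic"), candidates)
  sel <- which.min(qic)
  fit <- fits[[sel]]
  grid <- expand.grid(trial_type = levels(d$trial_type),
                      cost = levels(d$cost), KEEP.OUT.ATTRS = FALSE)
  cells <- stats::predict(fit, grid)
  names(cells)[names(cells) == "cost"] <- "cost_level"
  out <- list(task = task, qic = qic,
              working_correlation = candidates[sel], fit = fit,
              wald = gee_wald(fit), cells = cells,
              interaction = interaction)
  class(out) <- "achievement_regression"
  out
}

#' @export
print.achievement_regression <- function(x, ...) {
  cat(sprintf("achievement regression (%s task): working correlation %s (QIC %s)\n",
              x$task, x$working_correlation,
              paste(sprintf("%s %.1f", names(x$qic), x$qic), collapse = ", ")))
  print(x$wald, row.names = FALSE)
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Behavioural rates per subject and aggregate
#'
#' Precommitment rate (precommitted / precommitment trials), opt-out rate
#' (opt-outs / standard-trial LR choices, with the per-standard-trial rate
#' also reported), achieved-LR proportions per trial type, and the
#' precommitment benefit: the relative increase in achieved LRs in
#' precommitment over standard trials.
#'
#' @param trials Trial-record data.frame.
#' @return A list of class `rates_report`: `per_subject` (one row per
#'   subject x task), `aggregate` (pooled per task), `cells` (achieved-LR
#'   proportion per task x trial type x cost level). Undefined rates
#'   (zero denominators) are `NA`.
#' @export
behavioral_rates <- function(trials) {
  prop <- function(num, den) if (den > 0) num / den else NA_real_
  one <- function(d) {
    pre <- d[d$trial_type == "precommitment", ]
    std <- d[d$trial_type == "standard", ]
    std_lr <- std[std$choice == "LR", ]
    ach_std <- prop(sum(std$achieved_LR), nrow(std))
    ach_pre <- prop(sum(pre$achieved_LR), nrow(pre))
    data.frame(
      n_trials = nrow(d),
      precommit_rate = prop(sum(pre$precommit == "yes", na.rm = TRUE),
                            nrow(pre)),
      opt_out_rate = prop(sum(std_lr$opt_out), nrow(std_lr)),
      opt_out_rate_trials = prop(sum(std$opt_out), nrow(std)),
      achieved_standard = ach_std,
      achieved_precommitment = ach_pre,
      precommit_benefit = if (!is.na(ach_std) && ach_std > 0)
        (ach_pre - ach_std) / ach_std else NA_real_,
      stringsAsFactors = FALSE)
  }
  combos <- unique(trials[c("subject_id", "task")])
  per_subject <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    d <- trials[trials$subject_id == combos$subject_id[i] &
                  trials$task == combos$task[i], ]
    cbind(combos[i, ], one(d), row.names = NULL)
  }))
  aggregate <- do.call(rbind, lapply(unique(trials$task), function(tk) {
    cbind(data.frame(task = tk), one(trials[trials$task == tk, ]),
          row.names = NULL)
  }))
  cells <- stats::aggregate(achieved_LR ~ task + trial_type + cost_level,
                            data = trials, FUN = mean)
  names(cells)[names(cells) == "achieved_LR"] <- "achieved_prop"
  out <- list(per_subject = per_subject, aggregate = aggregate,
              cells = cells)
  class(out) <- "rates_report"
  out
}

#' @export
print.rates_report <- function(x, ...) {
  cat("behavioural rates (aggregate):\n")
  print(x$aggregate, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Spearman rank correlation of a per-subject quantity across tasks
#'
#' @param effort,delay Paired per-subject values from the two tasks
#'   (same subject order).
#' @return A list with `rho`, `p` (two-tailed), `n`, and a `degenerate`
#'   flag set when either vector is constant (then `rho` is `NA`).
#' @export
cross_task_correlation <- function(effort, delay) {
  ok <- stats::complete.cases(effort, delay)
  x <- effort[ok]; y <- delay[ok]
  if (length(x) != length(y) || length(x) < 3)
    stop_config("cross_task_correlation: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}
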