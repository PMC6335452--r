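# Bayesian model comparison: BIC (with group BIC as the per-subject sum),
# McFadden pseudo-R2 against a chance-prediction null, and paired contrasts
# of fitted parameters.

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * logLik`; lower is better, and group differences
#' greater than 2 count as positive evidence.
#'
#' @param logLik Maximized log-likelihood (<= 0 for Bernoulli data).
#' @param k Number of free parameters.
#' @param n Number of trials.
#' @return Scalar BIC.
#' @export
bic <- function(logLik, k, n) {
  if (any(n < 1)) stop_config("bic: n must be >= 1")
  k * log(n) - 2 * logLik
}

#' Group BIC: sum of per-subject BIC scores
#'
#' @param fits Data.frame with columns `subject_id` and `bic`, one row per
#'   subject (e.g. a one-model slice of [fit_cohort()] output).
#' @return Scalar group BIC.
#' @export
group_bic <- function(fits) {
  if (anyDuplicated(fits$subject_id))
    stop_config("group_bic: duplicated subjects; pass one fit per subject")
  sum(fits$bic)
}

#' McFadden pseudo-R2 against a chance null
#'
#' `1 - logLik / logLik_null` with `logLik_null = n * ln(0.5)`, the
#' likelihood of predicting every binary outcome at chance. Values of 0.2
#' or higher are conventionally read as excellent fit.
#'
#' @param logLik Maximized log-likelihood.
#' @param n Number of trials.
#' @return Scalar in `[0, 1]` for any fit at least as good as chance.
#' @export
mcfadden_r2 <- function(logLik, n) {
  if (any(n < 1)) stop_config("mcfadden_r2: n must be >= 1")
  1 - logLik / (n * log(0.5))
}

# Paired t-test tolerant of zero-variance differences (returns NaN with a
# warning instead of erroring, so degenerate synthetic cohorts don't abort
# a comparison).
paired_t <- function(x, y, label = "contrast") {
  d <- x - y
  if (length(d) < 2 || isTRUE(all.equal(stats::var(d), 0)) ||
      stats::sd(d) == 0) {
    warning(sprintf("%s: zero variance in paired differences; t/p set to NaN",
                    label), call. = FALSE)
    return(list(mean_diff = mean(d), t = NaN, df = length(d) - 1, p = NaN))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Compare two fitted models across a cohort
#'
#' Computes per-subject BIC differences, group BICs and their difference,
#' mean pseudo-R2 per model with a paired two-tailed t-test, optional
#' paired contrasts of named parameters (e.g. `theta` between the two
#' precommitment models, or `iota` between choice- and reward-fitted WP
#' models), and the winner by lower group BIC with its evidence category
#' (`"positive"` when the absolute group difference exceeds 2).
#'
#' @param fits_a,fits_b Data.frames of per-subject fits for the two models
#'   (same subjects, one row each).
#' @param contrast_params Character vector of parameter columns to contrast
#'   with paired t-tests.
#' @param labels Length-2 model labels for reporting.
#' @param exclude_subjects Subject ids dropped before all computations
#'   (e.g. from [exclude_extreme_precommitters()]).
#' @return A list of class `model_comparison`.
#' @export
compare_models <- function(fits_a, fits_b, contrast_params = NULL,
                           labels = c(fits_a$model[1], fits_b$model[1]),
                           exclude_subjects = NULL) {
  if (!is.null(exclude_subjects)) {
    fits_a <- fits_a[!fits_a$subject_id %in% exclude_subjects, ]
    fits_b <- fits_b[!fits_b$subject_id %in% exclude_subjects, ]
  }
  fits_a <- fits_a[order(fits_a$subject_id), ]
  fits_b <- fits_b[order(fits_b$subject_id), ]
  if (nrow(fits_a) != nrow(fits_b) ||
      !identical(fits_a$subject_id, fits_b$subject_id))
    stop_config("compare_models: subject sets are not aligned")
  g_a <- group_bic(fits_a); g_b <- group_bic(fits_b)
  delta <- g_a - g_b
  contrasts <- list()
  for (p in contrast_params %||% character(0)) {
    if (is.null(fits_a[[p]]) || is.null(fits_b[[p]]))
      stop_config("contrast parameter not present in both fits: ", p)
    contrasts[[p]] <- paired_t(fits_a[[p]], fits_b[[p]], p)
  }
  out <- list(
    labels = labels,
    n_subjects = nrow(fits_a),
    delta_bic_subject = stats::setNames(fits_a$bic - fits_b$bic,
                                        fits_a$subject_id),
    group_bic = stats::setNames(c(g_a, g_b), labels),
    group_delta_bic = delta,
    mean_pseudo_r2 = stats::setNames(c(mean(fits_a$pseudo_r2),
                                       mean(fits_b$pseudo_r2)), labels),
    pseudo_r2_test = paired_t(fits_a$pseudo_r2, fits_b$pseudo_r2,
                              "pseudo_r2"),
    contrasts = contrasts,
    winner = if (delta < 0) labels[1] else if (delta > 0) labels[2] else NA,
    evidence = if (abs(delta) > 2) "positive" else "weak")
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("model comparison (%d subjects): %s vs %s\n", x$n_subjects,
              x$labels[1], x$labels[2]))
  cat(sprintf("  group BIC: %.1f vs %.1f (delta %.1f, winner %s, %s evidence)\n",
              x$group_bic[1], x$group_bic[2], x$group_delta_bic,
              x$winner, x$evidence))
  cat(sprintf("  mean pseudoR2: %.3f vs %.3f (t = %.3f, p = %.4g)\n",
              x$mean_pseudo_r2[1], x$mean_pseudo_r2[2],
              x$pseudo_r2_test$t, x$pseudo_r2_test$p))
  for (p in names(x$contrasts))
    cat(sprintf("  %s: mean diff %.3f (t = %.3f, df = %d, p = %.4g)\n", p,
                x$contrasts[[p]]$mean_diff, x$contrasts[[p]]$t,
                x$contrasts[[p]]$df, x$contrasts[[p]]$p))
  invisible(x)
}

#' Subjects who always or never accepted precommitment
#'
#' The theta contrast between the two precommitment models is optionally
#' re-run after excluding these subjects, whose precommitment decisions
#' carry no information about value sensitivity.
#'
#' @param trials Trial-record data.frame.
#' @param task Optional task filter.
#' @return Character vector of subject ids.
#' @export
exclude_extreme_precommitters <- function(trials, task = NULL) {
  d <- trials[trials$trial_type == "precommitment", ]
  if (!is.null(task)) d <- d[d$task %in% task, ]
  rates <- tapply(d$precommit == "yes", d$subject_id, mean)
  names(rates)[rates %in% c(0, 1)]
}
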