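# Orchestration: power analysis, configuration handling, and the
# end-to-end pipeline (simulate -> model-free -> fit -> compare ->
# correlate -> optional recovery).

#' Required sample size for a paired t-test
#'
#' Smallest `n` such that a paired-samples t-test at significance level
#' `alpha` reaches the target power for a standardized effect `d_z`, using
#' the exact noncentral-t distribution (noncentrality `d_z * sqrt(n)`,
#' `n - 1` degrees of freedom). With the defaults of a moderate effect
#' (`d_z = 0.5`), `alpha = 0.05` two-tailed and power 0.95, the answer
#' is 54.
#'
#' @param d_z Standardized effect size of the paired differences (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param tails 1 or 2.
#' @param n_max Search ceiling (a config error is raised if the power is
#'   not reached by then).
#' @return Integer sample size (>= 2).
#' @examples
#' run_power_analysis(0.5)  # 54
#' @export
run_power_analysis <- function(d_z, alpha = 0.05, power = 0.95, tails = 2,
                               n_max = 1e6) {
  if (d_z <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_config("require d_z > 0 and alpha, power in (0, 1)")
  if (!tails %in% c(1, 2)) stop_config("tails must be 1 or 2")
  achieved <- function(n) {
    crit <- stats::qt(1 - alpha / tails, n - 1)
    ncp <- d_z * sqrt(n)
    pow <- stats::pt(crit, n - 1, ncp, lower.tail = FALSE)
    if (tails == 2) pow <- pow + stats::pt(-crit, n - 1, ncp)
    pow
  }
  for (n in 2:n_max) if (achieved(n) >= power) return(as.integer(n))
  stop_config("target power unreachable below n_max")
}

#' Default pipeline configuration
#'
#' @param n_subjects Cohort size (58 matches the analysed sample).
#' @param seed Global seed; every random stage derives its own seed from
#'   it deterministically.
#' @return Nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(n_subjects = 58, seed = 1) {
  list(seed = seed,
       simulate = list(n_subjects = n_subjects,
                       tasks = c("effort", "delay"),
                       generative_model = "MM",
                       design_reps = 10),
       data = NULL,  # or list(trials_csv = ..., rewards_csv = ...)
       fit = list(n_starts = 20),
       comparison = list(exclude_extreme = TRUE),
       recovery = list(enabled = FALSE, n_reps = 5,
                       trials_per_subject = 600),
       output_dir = NULL)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults of [default_config()].
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                  simplifyVector = TRUE)
         else stop_config("config must be .yaml/.yml or .json")
  base <- default_config()
  merge_cfg <- function(base, new) {
    for (nm in names(new))
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        merge_cfg(base[[nm]], new[[nm]]) else new[[nm]]
    base
  }
  merge_cfg(base, cfg)
}

#' Run the full analysis pipeline
#'
#' Stages: obtain trial data (simulate a synthetic cohort, or load CSVs
#' named in `config$data`), model-free rates and achievement regressions,
#' per-subject model fitting, model comparisons (choice pair, willpower
#' contrast `iota_choice` vs `iota_reward`, precommitment pair with theta
#' contrast, optionally re-run without always/never precommitters),
#' cross-task Spearman correlations of the precommitment bias and benefit,
#' and an optional parameter-recovery study. All stochastic stages derive
#' their seeds from `config$seed`, so the report is reproducible.
#'
#' @param config Configuration list ([default_config()]) or a path to a
#'   YAML/JSON file ([read_config()]).
#' @return A list of class `run_report` with elements `rates`,
#'   `regression`, `fits`, `comparisons`, `correlations`, `recovery`,
#'   `degenerate_subjects`, `provenance`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed %||% 1
  # --- data ---
  if (!is.null(config$data)) {
    trials <- read_trials_csv(config$data$trials_csv)
    rewards <- utils::read.csv(config$data$rewards_csv,
                               stringsAsFactors = FALSE)
    cohort <- NULL
  } else {
    sim <- config$simulate
    pc <- sim$prior_config %||%
      default_prior_config(sim$generative_model %||% "MM")
    cohort <- simulate_cohort(sim$n_subjects, tasks = sim$tasks,
                              prior_config = pc,
                              design_reps = sim$design_reps %||% 10,
                              seed = derive_seed(seed, "simulate"))
    trials <- cohort$trials
    rewards <- unique(cohort$subjects[c("subject_id", "M_LR", "M_SR")])
  }
  tasks <- intersect(c("effort", "delay"), unique(trials$task))
  # --- model-free ---
  rates <- behavioral_rates(trials)
  regression <- lapply(stats::setNames(tasks, tasks), function(tk)
    achievement_regression(trials, tk))
  # --- fitting ---
  fits <- fit_cohort(trials, rewards,
                     n_starts = config$fit$n_starts %||% 20,
                     seed = derive_seed(seed, "fit"))
  # --- comparisons ---
  comparisons <- lapply(stats::setNames(tasks, tasks), function(tk) {
    f <- fits[fits$task == tk, ]
    choice <- compare_models(
      f[f$model == "MM_choice" & f$outcome == "choice", ],
      f[f$model == "WP_choice" & f$outcome == "choice", ])
    wp_ch <- f[f$model == "WP_choice" & f$outcome == "choice", ]
    wp_re <- f[f$model == "WP_choice" & f$outcome == "achievement", ]
    wp_ch <- wp_ch[order(wp_ch$subject_id), ]
    wp_re <- wp_re[order(wp_re$subject_id), ]
    iota_test <- paired_t(wp_ch$iota, wp_re$iota, "iota_choice vs iota_reward")
    precom <- compare_models(f[f$model == "MM_precom", ],
                             f[f$model == "WP_precom", ],
                             contrast_params = "theta")
    out <- list(choice = choice, iota_test = iota_test, precom = precom)
    if (isTRUE(config$comparison$exclude_extreme)) {
      excl <- exclude_extreme_precommitters(trials, tk)
      if (length(excl) && length(excl) < precom$n_subjects - 2)
        out$precom_excluded <- compare_models(
          f[f$model == "MM_precom", ], f[f$model == "WP_precom", ],
          contrast_params = "theta", exclude_subjects = excl)
      out$excluded_subjects <- excl
    }
    out
  })
  # --- cross-task correlations ---
  correlations <- NULL
  if (all(c("effort", "delay") %in% tasks)) {
    b_eff <- fits[fits$model == "MM_precom" & fits$task == "effort", ]
    b_del <- fits[fits$model == "MM_precom" & fits$task == "delay", ]
    b_eff <- b_eff[order(b_eff$subject_id), ]
    b_del <- b_del[order(b_del$subject_id), ]
    ps <- rates$per_subject
    ben_e <- ps[ps$task == "effort", ]; ben_e <- ben_e[order(ben_e$subject_id), ]
    ben_d <- ps[ps$task == "delay", ]; ben_d <- ben_d[order(ben_d$subject_id), ]
    correlations <- list(
      b = cross_task_correlation(b_eff$b, b_del$b),
      precommit_benefit = cross_task_correlation(ben_e$precommit_benefit,
                                                 ben_d$precommit_benefit))
  }
  # --- optional recovery ---
  recovery <- NULL
  if (isTRUE(config$recovery$enabled)) {
    grid <- expand.grid(discount = c(0.1, 0.3), gamma = c(5, 15),
                        KEEP.OUT.ATTRS = FALSE)
    recovery <- recovery_study("MM_choice", grid,
                               trials_per_subject =
                                 config$recovery$trials_per_subject %||% 600,
                               n_reps = config$recovery$n_reps %||% 5,
                               seed = derive_seed(seed, "recovery"))
  }
  report <- list(rates = rates, regression = regression, fits = fits,
                 comparisons = comparisons, correlations = correlations,
                 recovery = recovery,
                 degenerate_subjects = flag_degenerate_subjects(trials),
                 provenance = list(seed = seed, config = config,
                                   n_trials = nrow(trials),
                                   tasks = tasks))
  class(report) <- "run_report"
  if (!is.null(config$output_dir)) write_run_report(report, trials,
                                                    config$output_dir)
  report
}

# Persist the tabular outputs of a pipeline run.
write_run_report <- function(report, trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials_csv(trials, file.path(dir, "trials.csv"))
  utils::write.csv(report$fits, file.path(dir, "fits.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$rates$per_subject,
                   file.path(dir, "rates_per_subject.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(report$rates$aggregate,
                   file.path(dir, "rates_aggregate.csv"),
                   row.names = FALSE, na = "")
  for (tk in names(report$regression))
    utils::write.csv(report$regression[[tk]]$cells,
                     file.path(dir, paste0("regression_cells_", tk, ".csv")),
                     row.names = FALSE, na = "")
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== pipeline report ==\n")
  cat(sprintf("seed %s; %d trial records; tasks: %s\n",
              x$provenance$seed, x$provenance$n_trials,
              paste(x$provenance$tasks, collapse = ", ")))
  print(x$rates)
  for (tk in names(x$regression)) print(x$regression[[tk]])
  for (tk in names(x$comparisons)) {
    cat(sprintf("-- %s task --\n", tk))
    print(x$comparisons[[tk]]$choice)
    it <- x$comparisons[[tk]]$iota_test
    cat(sprintf("  iota_choice vs iota_reward: mean diff %.3f (t = %.3f, p = %.4g)\n",
                it$mean_diff, it$t, it$p))
    print(x$comparisons[[tk]]$precom)
  }
  if (!is.null(x$correlations)) {
    cat(sprintf("cross-task Spearman: b rho = %.3f (p = %.4g); benefit rho = %.3f (p = %.4g)\n",
                x$correlations$b$rho, x$correlations$b$p,
                x$correlations$precommit_benefit$rho,
                x$correlations$precommit_benefit$p))
  }
  if (!is.null(x$recovery)) print(x$recovery)
  if (nrow(x$degenerate_subjects))
    cat(sprintf("%d degenerate (no choice variance) subject-task cases flagged\n",
                nrow(x$degenerate_subjects)))
  invisible(x)
}
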