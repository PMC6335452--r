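# Task designs and subject-level reward sets.

#' Default cost levels for a task
#'
#' Effort task: 2, 4 or 6 dynamometer squeezes; delay task: 4, 7 or 10 s of
#' waiting.
#'
#' @param task `"effort"` or `"delay"`.
#' @return Numeric vector of cost levels.
#' @export
default_cost_levels <- function(task = c("effort", "delay")) {
  task <- match.arg(task)
  if (task == "effort") c(2, 4, 6) else c(4, 7, 10)
}

#' Generate a randomized task design
#'
#' Builds the trial sequence for one session of one task: every combination
#' of trial type (standard, precommitment) and cost level appears exactly
#' `reps` times, in a single seeded uniform shuffle. The default
#' configuration (3 cost levels, 10 reps) yields the full 60-trial session
#' with 30 standard and 30 precommitment trials.
#'
#' @param task `"effort"` or `"delay"`.
#' @param cost_levels Cost levels of the large reward; defaults to
#'   [default_cost_levels()].
#' @param reps Repetitions of each (trial type, cost level) cell.
#' @param seed Integer seed for the shuffle.
#' @return A `data.frame` of class `task_design` with columns `task`,
#'   `trial_index` (0-based, unique), `trial_type`, `cost_level`.
#' @examples
#' d <- generate_task_design("effort", seed = 1)
#' table(d$trial_type, d$cost_level)
#' @export
generate_task_design <- function(task = c("effort", "delay"),
                                 cost_levels = default_cost_levels(task),
                                 reps = 10, seed = 1) {
  task <- match.arg(task)
  if (length(cost_levels) < 1) stop_config("cost_levels must be non-empty")
  if (anyDuplicated(cost_levels)) stop_config("cost_levels must be distinct")
  if (any(cost_levels <= 0)) stop_config("cost_levels must be positive")
  if (!is.numeric(reps) || reps < 1 || reps != round(reps))
    stop_config("reps must be an integer >= 1")

  grid <- expand.grid(trial_type = c("standard", "precommitment"),
                      cost_level = cost_levels,
                      rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ord <- with_seed(seed, sample.int(nrow(grid)))
  out <- data.frame(task = task,
                    trial_index = seq_len(nrow(grid)) - 1L,
                    trial_type = grid$trial_type[ord],
                    cost_level = grid$cost_level[ord],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("task_design", class(out))
  out
}

#' Build a subject's reward set from image ratings
#'
#' Ratings of 0 ("not enjoyable") or 1 ("neutral") are discarded; of the
#' retained ratings, items strictly above their median become large rewards
#' and items strictly below it small rewards (items exactly at the median
#' belong to neither set). The reward magnitudes `M_LR` and `M_SR` are the
#' mean retained ratings of the two sets.
#'
#' @param ratings Numeric vector of item ratings on the 0-10 scale.
#' @return A list of class `reward_set` with elements `M_LR`, `M_SR`,
#'   `n_LR`, `n_SR`.
#' @examples
#' build_reward_set(1:9)  # M_LR = 7.5, M_SR = 3.5
#' @export
build_reward_set <- function(ratings) {
  if (!is.numeric(ratings) || !length(ratings))
    stop_config("ratings must be a non-empty numeric vector")
  if (any(is.na(ratings)) || any(ratings < 0) || any(ratings > 10))
    stop_config("ratings must lie in [0, 10]")
  kept <- ratings[ratings > 1]
  if (length(kept) < 2)
    stop_config("degenerate ratings: fewer than two items retained after discarding ratings <= 1")
  med <- stats::median(kept)
  lr <- kept[kept > med]
  sr <- kept[kept < med]
  if (!length(lr) || !length(sr))
    stop_config("degenerate ratings: no strict large/small reward split exists")
  out <- list(M_LR = mean(lr), M_SR = mean(sr),
              n_LR = length(lr), n_SR = length(sr))
  class(out) <- "reward_set"
  out
}

#' @export
print.reward_set <- function(x, ...) {
  cat(sprintf("reward set: M_LR = %.3f (n = %d), M_SR = %.3f (n = %d)\n",
              x$M_LR, x$n_LR, x$M_SR, x$n_SR))
  invisible(x)
}
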