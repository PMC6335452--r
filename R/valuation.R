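# Value computations shared by both candidate accounts of precommitment.
#
# Both accounts assume hyperbolic discounting of the costly large reward (LR)
# by its effort or delay requirement, SV = M / (1 + k * cost), and map value
# differences onto choice probabilities with a logistic (softmax) rule.
# They differ in how the effort-free/immediate small reward (SR) enters:
#   * motivation maximization (MM): the SR's full subjective value acts as an
#     opportunity cost, dV = SV_LR - SV_SR;
#   * willpower (WP): the SR's value is wilfully suppressed by a factor
#     iota in [0, 1] during choice, dV = SV_LR - iota * SV_SR.

#' Hyperbolically discounted subjective value
#'
#' Computes `SV = M / (1 + k * cost)`, the subjective value of a reward of
#' magnitude `M` whose receipt requires `cost` units of effort (dynamometer
#' squeezes) or delay (seconds), with discount rate `k` (the effort rate
#' epsilon or the delay rate kappa).
#'
#' @param M Reward magnitude(s), non-negative (subject-specific mean image
#'   rating on the 0-10 scale).
#' @param cost Effort or delay requirement(s), non-negative.
#' @param k Discount rate, non-negative.
#' @return Subjective value(s), in `(0, M]`.
#' @examples
#' subjective_value(8, cost = 4, k = 0.25)  # 4
#' @export
subjective_value <- function(M, cost, k) {
  if (any(M < 0) || any(cost < 0) || any(k < 0) ||
      any(!is.finite(M)) || any(!is.finite(cost)) || any(!is.finite(k)))
    stop_config("subjective_value: M, cost and k must be finite and non-negative")
  M / (1 + k * cost)
}

#' Net motivational value of the LR option (motivation maximization)
#'
#' `dV = SV_LR - SV_SR`, where the opportunity cost of choosing the costly
#' large reward is the full (undiscounted) subjective value of the free small
#' reward, `SV_SR = M_SR`.
#'
#' @param M_LR,M_SR Large- and small-reward magnitudes.
#' @param cost Effort/delay requirement of the LR.
#' @param k Discount rate.
#' @return Net value(s) `dV`.
#' @export
net_value_mm <- function(M_LR, M_SR, cost, k) {
  subjective_value(M_LR, cost, k) - M_SR
}

#' Net motivational value of the LR option (willpower)
#'
#' `dV = SV_LR - iota * SV_SR`: the small reward's value is suppressed by the
#' willpower factor `iota` during choice (`iota = 0` complete suppression,
#' `iota = 1` none; at `iota = 1` this reduces exactly to [net_value_mm()]).
#'
#' @inheritParams net_value_mm
#' @param iota Willpower suppression factor in `[0, 1]`.
#' @return Net value(s) `dV`.
#' @export
net_value_wp <- function(M_LR, M_SR, cost, k, iota) {
  if (missing(iota) || is.null(iota) || any(is.na(iota)))
    stop_config("net_value_wp: the willpower parameter 'iota' is required")
  if (any(iota < 0) || any(iota > 1))
    stop_config("net_value_wp: 'iota' must lie in [0, 1]")
  subjective_value(M_LR, cost, k) - iota * M_SR
}

#' Softmax probability of choosing the costly large reward
#'
#' `P(choice = LR) = 1 / (1 + exp(-gamma * dV))`. Evaluated through
#' [stats::plogis()], which is overflow-safe for arbitrarily large
#' `|gamma * dV|`.
#'
#' @param dV Net motivational value(s) of the LR option.
#' @param gamma Inverse temperature, non-negative; `gamma = 0` yields 0.5.
#' @return Choice probability/probabilities.
#' @export
p_choice_lr <- function(dV, gamma) {
  if (any(gamma < 0)) stop_config("p_choice_lr: 'gamma' must be non-negative")
  stats::plogis(gamma * dV)
}

#' Value of precommitment under motivation maximization
#'
#' `V = SV_LR - SV_SR`: precommitting (removing the SR) pays off exactly when
#' the costly large reward is the higher-valued option, because it eliminates
#' the opportunity cost that drags down net motivation.
#'
#' @param sv_lr,sv_sr Subjective values of the LR and SR options.
#' @return Precommitment value(s).
#' @export
v_precom_mm <- function(sv_lr, sv_sr) sv_lr - sv_sr

#' Value of precommitment under the willpower account
#'
#' `V = iota_reward * SV_SR - SV_LR`: precommitment is worthwhile when even
#' the suppressed small-reward value exceeds the large reward's value, i.e.
#' when a willpower failure is anticipated.
#'
#' @param sv_lr,sv_sr Subjective values of the LR and SR options.
#' @param iota_reward Willpower factor estimated from achieved rewards.
#' @return Precommitment value(s).
#' @export
v_precom_wp <- function(sv_lr, sv_sr, iota_reward) {
  if (any(iota_reward < 0) || any(iota_reward > 1))
    stop_config("v_precom_wp: 'iota_reward' must lie in [0, 1]")
  iota_reward * sv_sr - sv_lr
}

#' Probability of accepting precommitment
#'
#' `P(precommit) = 1 / (1 + exp(-(theta * V + b)))`, where `theta` scales the
#' sensitivity of the decision to the precommitment value `V` and `b` is a
#' value-independent bias. Overflow-safe.
#'
#' @param V Precommitment value(s).
#' @param theta Sensitivity (inverse temperature), non-negative.
#' @param b Bias term.
#' @return Precommitment probability/probabilities.
#' @export
p_precommit <- function(V, theta, b) {
  if (any(theta < 0)) stop_config("p_precommit: 'theta' must be non-negative")
  stats::plogis(theta * V + b)
}
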