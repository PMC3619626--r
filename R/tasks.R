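# Generalized-utility evaluation: how well does a learned internal model
# support goal-directed tasks it was never trained on?  The agent's model is
# snapshotted, a task-optimal policy is derived *under the model*, and that
# policy's realized performance under the true world is compared with the
# true-optimal policy.  Evaluation never mutates the model.

#' @noRd
as_theta <- function(x) {
  if (inherits(x, "posterior_model")) x$theta_hat
  else if (inherits(x, "cmc_kernel")) x$theta
  else x
}

#' Navigation loss of an internal model
#'
#' For every (start, target) pair the model's hitting policy (the policy
#' minimizing expected steps under `model_theta`) is evaluated in the true
#' world, and the excess over the true-optimal expected steps is averaged.
#' Expected step counts saturate at `max_steps` (see
#' [optimal_hitting_policy()]); pairs the true-optimal policy cannot reach
#' are excluded from the average, and a model policy that fails to reach a
#' reachable target pays the saturated penalty rather than an infinite one.
#'
#' @param model_theta internal model: a `posterior_model`, `cmc_kernel`, or
#'   `[a, s, s']` probability array.
#' @param world the true `cmc_kernel`.
#' @param max_steps saturation ceiling (default `10 * n_states`).
#' @return mean navigation loss in expected extra steps (>= 0), with the
#'   number of excluded pairs as attribute `n_excluded`.
#' @export
navigation_loss <- function(model_theta, world, max_steps = NULL) {
  mth <- as_theta(model_theta)
  N <- world$n_states
  if (!identical(dim(mth), dim(world$theta))) stop_invalid("shape mismatch")
  if (is.null(max_steps)) max_steps <- default_step_cap(N)
  hv_true <- hitting_values_all(world$theta, cap = max_steps)
  hv_model <- hitting_values_all(mth, cap = max_steps)
  loss <- 0; n_inc <- 0L; n_exc <- 0L
  for (target in seq_len(N)) {
    v_opt <- hv_true$values[, target]
    v_real <- policy_hitting_values(world$theta, hv_model$policy[, target],
                                    target, cap = max_steps)
    for (s in seq_len(N)) {
      if (s == target) next
      if (v_opt[s] >= max_steps - 1e-6) { n_exc <- n_exc + 1L; next }
      loss <- loss + max(v_real[s] - v_opt[s], 0)
      n_inc <- n_inc + 1L
    }
  }
  if (n_inc == 0L) stop_invalid("no reachable (start, target) pair to average over")
  structure(loss / n_inc, n_excluded = n_exc)
}

# Finite-horizon undiscounted reward planning: backward value iteration
# under `theta`, collecting the reward of each state entered.  Returns the
# start-state values and the time-indexed greedy policy [state, time].
#' @noRd
reward_plan <- function(theta, rewards, horizon) {
  M <- dim(theta)[1]; N <- dim(theta)[2]
  v <- rep(0, N)
  pol <- matrix(1L, N, horizon)
  for (t in horizon:1) {
    qa <- matrix(0, N, M)
    for (a in seq_len(M)) qa[, a] <- theta[a, , ] %*% (rewards + v)
    pol[, t] <- max.col(qa, ties.method = "first")
    v <- qa[cbind(seq_len(N), pol[, t])]
  }
  list(values = v, policy = pol)
}

# Realized expected cumulative reward of a time-indexed policy under the
# true kernel.
#' @noRd
reward_evaluate <- function(theta, rewards, policy) {
  N <- dim(theta)[2]
  horizon <- ncol(policy)
  v <- rep(0, N)
  for (t in horizon:1) {
    vn <- numeric(N)
    for (s in seq_len(N)) {
      row <- theta[policy[s, t], s, ]
      vn[s] <- sum(row * (rewards + v))
    }
    v <- vn
  }
  v
}

#' Reward loss of an internal model
#'
#' The agent plans a 100-step (undiscounted) reward-gathering policy by
#' finite-horizon value iteration under its internal model; the reward of
#' each state entered is collected.  That time-indexed policy is then
#' evaluated exactly under the true world and compared with the
#' true-optimal plan, averaging the forgone reward over all starting
#' states.
#'
#' @inheritParams navigation_loss
#' @param rewards numeric reward per state.
#' @param horizon number of steps (default 100).
#' @return mean expected reward forgone (>= 0 up to solver tolerance).
#' @export
reward_loss <- function(model_theta, world, rewards, horizon = 100) {
  mth <- as_theta(model_theta)
  if (!identical(dim(mth), dim(world$theta))) stop_invalid("shape mismatch")
  if (horizon < 1) stop_invalid("horizon must be >= 1")
  if (length(rewards) != world$n_states)
    stop_invalid("need one reward per state")
  plan_model <- reward_plan(mth, rewards, horizon)
  plan_true <- reward_plan(world$theta, rewards, horizon)
  realized <- reward_evaluate(world$theta, rewards, plan_model$policy)
  mean(pmax(plan_true$values - realized, 0))
}

#' Rank strategies by per-world losses
#'
#' Within each world, strategies are ranked ascending by loss (rank 1 =
#' best, ties receive their mean rank); the per-strategy ranks are then
#' averaged across worlds.
#'
#' @param losses named list: one numeric vector of per-world losses per
#'   strategy, all of equal length (same world set).
#' @return named numeric vector of mean ranks.
#' @export
rank_strategies <- function(losses) {
  if (length(losses) < 2) stop_invalid("need at least two strategies to rank")
  lens <- lengths(losses)
  if (length(unique(lens)) != 1)
    stop_invalid("all strategies must be scored on the same worlds")
  mat <- do.call(cbind, losses)
  ranks <- t(apply(mat, 1, rank, ties.method = "average"))
  if (nrow(mat) == 1) ranks <- matrix(ranks, nrow = 1, dimnames = list(NULL, names(losses)))
  colMeans(ranks)
}
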