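# Structural metrics of CMC worlds: equilibrium state bias, controllability,
# and expected path lengths, plus learning-curve comparisons.

# Random-action transition matrix T(s' | s) = mean over actions of the rows.
#' @noRd
random_action_chain <- function(world) {
  apply(world$theta, c(2, 3), mean)
}

#' Equilibrium distribution under random actions
#'
#' The long-run state distribution of an agent choosing actions uniformly
#' at random: the stationary distribution of
#' `T(s'|s) = (1/M) sum_a theta[a, s, s']`, computed by power iteration
#' from the uniform start until successive iterates differ by less than
#' `tol` in L1.  On reducible chains this converges to the limit selected
#' by the uniform initial condition.
#'
#' @param world a `cmc_kernel`.
#' @param tol L1 convergence tolerance (default 1e-12).
#' @param max_iter iteration cap (default 1e6); non-convergence is an error
#'   naming the world class.
#' @return probability vector over states.
#' @export
equilibrium_distribution <- function(world, tol = 1e-12, max_iter = 1e6) {
  tr <- random_action_chain(world)
  psi <- rep(1 / world$n_states, world$n_states)
  for (i in seq_len(max_iter)) {
    nxt <- as.vector(psi %*% tr)
    if (sum(abs(nxt - psi)) < tol) return(nxt)
    psi <- nxt
  }
  stop_invalid("equilibrium distribution failed to converge for this ",
               world$class_label, " world within ", max_iter, " iterations")
}

#' Structure index
#'
#' The state-occupancy bias of a world: the relative entropy deficit of its
#' random-walk equilibrium distribution,
#' `SI = (H(U) - H(psi)) / H(U)` with entropies in bits and
#' `H(U) = log2(N)`.  0 for an unbiased (uniform-equilibrium) world, 1 when
#' a single state absorbs all occupancy.
#'
#' @param psi probability vector (an equilibrium distribution).
#' @return structure index in \\[0, 1\\].
#' @export
structure_index <- function(psi) {
  n <- length(psi)
  if (n < 2) stop_invalid("structure index undefined for a single state")
  if (abs(sum(psi) - 1) > 1e-6) stop_invalid("psi must be normalized")
  hu <- log2s(n)
  (hu - entropy_bits(psi)) / hu
}

#' Control index (controllability at lag t)
#'
#' The mutual information, in bits, between a uniformly random first action
#' `a0` and the agent's state `t` steps later, averaged uniformly over
#' starting states.  After the first action the agent follows the uniform
#' random-action chain.  High values mean a single action choice shapes the
#' medium-term state trajectory.
#'
#' @param world a `cmc_kernel`.
#' @param t lag in steps (>= 1).
#' @return mutual information in bits (bounded by `log2(M)`).
#' @export
control_index <- function(world, t = 1) {
  if (t < 1) stop_invalid("t must be >= 1")
  N <- world$n_states; M <- world$n_actions
  tr <- random_action_chain(world)
  tpow <- diag(N)
  for (i in seq_len(t - 1)) tpow <- tpow %*% tr
  mi <- 0
  for (s0 in seq_len(N)) {
    cond <- world$theta[, s0, , drop = FALSE]
    dim(cond) <- c(M, N)
    cond <- cond %*% tpow               # p(s_t | a0, s0), rows = actions
    marg <- colMeans(cond)              # p(s_t | s0)
    pos <- cond > 0
    mi <- mi + sum(cond[pos] * log2s(cond[pos] / rep(marg, each = M)[pos])) / M
  }
  mi / N
}

# Capped stochastic-shortest-path value iteration for ALL targets at once.
# Returns V (N x N matrix, [start, target], expected steps saturating at
# `cap`) and the minimizing policy (N x N, [start, target]).
#' @noRd
hitting_values_all <- function(theta, cap, tol = 1e-9, max_iter = 20000L) {
  M <- dim(theta)[1]; N <- dim(theta)[2]
  v <- matrix(0, N, N)
  ea <- vector("list", M)
  for (i in seq_len(max_iter)) {
    for (a in seq_len(M)) ea[[a]] <- theta[a, , ] %*% v
    best <- ea[[1]]
    if (M > 1) for (a in 2:M) best <- pmin(best, ea[[a]])
    vnew <- pmin(1 + best, cap)
    diag(vnew) <- 0
    if (max(abs(vnew - v)) < tol) { v <- vnew; break }
    v <- vnew
  }
  pol <- matrix(1L, N, N)
  if (M > 1) {
    for (a in seq_len(M)) ea[[a]] <- theta[a, , ] %*% v
    best <- ea[[1]]
    for (a in 2:M) best <- pmin(best, ea[[a]])
    # ties resolve to the lowest action index (deterministic extraction)
    for (a in M:1) pol[ea[[a]] <= best + 1e-12] <- a
  }
  diag(pol) <- 1L
  list(values = v, policy = pol)
}

# Capped policy evaluation: expected steps to `target` under a fixed
# [start, target] policy column, evaluated in `theta`.
#' @noRd
policy_hitting_values <- function(theta, policy, target, cap, tol = 1e-9,
                                  max_iter = 20000L) {
  N <- dim(theta)[2]
  p <- matrix(0, N, N)
  for (s in seq_len(N)) p[s, ] <- theta[policy[s], s, ]
  v <- rep(0, N)
  for (i in seq_len(max_iter)) {
    vnew <- pmin(1 + as.vector(p %*% v), cap)
    vnew[target] <- 0
    if (max(abs(vnew - v)) < tol) { v <- vnew; break }
    v <- vnew
  }
  v
}

#' @noRd
default_step_cap <- function(n_states) 10 * n_states

#' Optimal hitting policy and expected path lengths
#'
#' Solves the stochastic-shortest-path problem to `target` by value
#' iteration on `V(s) = 1 + min_a sum_s' theta[a, s, s'] V(s')` with
#' `V(target) = 0`.  Expected step counts saturate at a ceiling
#' `max_steps` (default `10 * N`): states whose value reaches the ceiling
#' cannot reach the target (or can only reach it so unreliably that the
#' expected time exceeds the ceiling, as past an absorbing trap) and are
#' reported as `Inf`.
#'
#' @param world a `cmc_kernel`.
#' @param target target state index.
#' @param max_steps saturation ceiling for expected steps (default
#'   `10 * n_states`).
#' @return list with `policy` (action per state) and `expected_steps`
#'   (numeric per state, `Inf` for unreachable states; 0 at the target).
#' @export
optimal_hitting_policy <- function(world, target, max_steps = NULL) {
  N <- world$n_states
  if (target < 1 || target > N) stop_invalid("target out of range")
  if (is.null(max_steps)) max_steps <- default_step_cap(N)
  hv <- hitting_values_all(world$theta, cap = max_steps)
  v <- hv$values[, target]
  v[v >= max_steps - 1e-6] <- Inf
  list(policy = hv$policy[, target], expected_steps = v)
}

#' Mean path length of a world
#'
#' The average, over all ordered (start, target) pairs with start != target
#' and finite optimal expected path length, of the minimum expected number
#' of steps between them (see [optimal_hitting_policy()]).  The number of
#' excluded (unreachable) pairs is attached as attribute `n_excluded`.
#'
#' @inheritParams optimal_hitting_policy
#' @return mean expected path length with attribute `n_excluded`.
#' @export
mean_path_length <- function(world, max_steps = NULL) {
  N <- world$n_states
  if (is.null(max_steps)) max_steps <- default_step_cap(N)
  hv <- hitting_values_all(world$theta, cap = max_steps)
  v <- hv$values
  diag(v) <- NA                                  # start == target excluded
  v[v >= max_steps - 1e-6] <- NA
  vals <- v[!is.na(v)]
  if (length(vals) == 0)
    stop_invalid("no (start, target) pair is reachable in this world")
  structure(mean(vals), n_excluded = sum(is.na(v)) - N)
}

#' Embodiment index of a pair of learning curves
#'
#' The relative difference between the areas under the missing-information
#' learning curves of the embodied greedy-PIG agent and the unembodied
#' control: `(AUC_greedy - AUC_unembodied) / AUC_unembodied`, with AUCs by
#' the trapezoidal rule over the shared evaluation grid.  Near 0 when
#' embodiment costs nothing; large and positive when being confined to its
#' current state slows the agent down.
#'
#' @param curve_greedy,curve_unembodied `exploration_trace` objects with
#'   identical `eval_times`.
#' @return the embodiment index (dimensionless).
#' @export
embodiment_index <- function(curve_greedy, curve_unembodied) {
  if (!identical(curve_greedy$eval_times, curve_unembodied$eval_times))
    stop_invalid("traces must share the same evaluation grid")
  auc_g <- trapezoid_auc(curve_greedy$eval_times, curve_greedy$missing_info)
  auc_u <- trapezoid_auc(curve_unembodied$eval_times, curve_unembodied$missing_info)
  (auc_g - auc_u) / auc_u
}

#' Structural metrics of a world
#'
#' Convenience wrapper computing the structure index, control index at a
#' set of lags, and the mean path length of one world.
#'
#' @param world a `cmc_kernel`.
#' @param lags integer lags for the control index (default 1:10).
#' @return a one-row data frame.
#' @export
world_metrics <- function(world, lags = 1:10) {
  psi <- equilibrium_distribution(world)
  ci <- vapply(lags, function(t) control_index(world, t), numeric(1))
  mpl <- mean_path_length(world)
  out <- data.frame(world_class = world$class_label,
                    structure_index = structure_index(psi),
                    mean_path_length = as.numeric(mpl),
                    n_unreachable_pairs = attr(mpl, "n_excluded"))
  for (i in seq_along(lags)) out[[paste0("control_t", lags[i])]] <- ci[i]
  out
}
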