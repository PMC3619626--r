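# Action-selection policies and the exploration loop.
#
# The choose_* functions implement each policy's single decision in plain R;
# run_exploration() drives whole runs through the compiled engine in
# src/explore.cpp, which reimplements the same update rules for speed.  The
# test suite replays compiled traces against the R components to keep the
# two in lock-step.

# registry: name -> engine codes and default hyperparameters
STRATEGY_REGISTRY <- list(
  random       = list(code = 0L, utility = "pig"),
  unembodied   = list(code = 1L, utility = "pig"),
  pig_greedy   = list(code = 2L, utility = "pig"),
  pmc_greedy   = list(code = 2L, utility = "pmc"),
  plc_greedy   = list(code = 2L, utility = "plc"),
  pig_vi       = list(code = 3L, utility = "pig"),
  pmc_vi       = list(code = 3L, utility = "pmc"),
  plc_vi       = list(code = 3L, utility = "plc"),
  pig_vi_plus  = list(code = 3L, utility = "pig", vi_true_kernel = TRUE),
  lta          = list(code = 4L, utility = "pig"),
  cb           = list(code = 5L, utility = "pig"),
  peig_q       = list(code = 6L, utility = "pig")
)

UTILITY_CODES <- c(pig = 0L, pmc = 1L, plc = 2L)

#' Registered exploration strategies
#'
#' @return character vector of strategy labels accepted by
#'   [run_exploration()].
#' @export
exploration_strategies <- function() names(STRATEGY_REGISTRY)

# Normalize a strategy argument (label or list(name = ..., params...)) into
# a full spec with engine codes.
#' @noRd
as_strategy <- function(strategy) {
  if (is.character(strategy)) strategy <- list(name = strategy)
  name <- strategy$name
  if (is.null(name) || !name %in% names(STRATEGY_REGISTRY))
    stop_invalid("unknown strategy: ", if (is.null(name)) "<missing>" else name,
                 " (see exploration_strategies())")
  spec <- utils::modifyList(
    list(name = name, vi_true_kernel = FALSE, gamma = 0.95, horizon = 10L,
         learning_rate = 0.1, epsilon = 0.1),
    utils::modifyList(STRATEGY_REGISTRY[[name]], strategy[names(strategy) != "name"]))
  spec$name <- name
  spec
}

#' Uniformly random action
#'
#' The negative-control policy: ignores the state and model entirely.
#'
#' @param n_actions number of actions.
#' @return an action index.
#' @export
choose_random <- function(n_actions) sample.int(n_actions, 1L)

#' Unembodied control choice
#'
#' The positive control may teleport: it selects the globally best
#' (action, state) pair by predicted information gain, ties broken uniformly
#' at random.  The runner relocates the agent to the chosen state before
#' sampling the transition.
#'
#' @param model a `posterior_model`.
#' @return list with elements `action` and `state`.
#' @export
choose_unembodied <- function(model) {
  tab <- utility_table(model, "pig")
  idx <- argmax_tie(as.vector(tab))            # column-major: a fast, s slow
  a <- (idx - 1L) %% model$n_actions + 1L
  s <- (idx - 1L) %/% model$n_actions + 1L
  list(action = a, state = s)
}

#' Greedy action on a utility table
#'
#' Picks `argmax_a utility[a, s]`, ties broken uniformly at random.
#'
#' @param utility a `utility_table` (or any `[action, state]` matrix).
#' @param s current state.
#' @return an action index.
#' @export
choose_greedy <- function(utility, s) {
  if (s < 1 || s > ncol(utility)) stop_invalid("state index out of range")
  argmax_tie(utility[, s])
}

#' Finite-horizon value iteration over a utility table
#'
#' Coordinates actions over time: starting from `Q_0 = utility`, performs
#' `horizon` backward steps of
#' `Q(a, s) <- utility(a, s) + gamma * sum_s' kernel[a, s, s'] max_a' Q(a', s')`
#' and returns the resulting Q table.  The backup kernel is the agent's
#' internal model for PIG(VI)/PMC(VI)/PLC(VI) and the true world kernel for
#' the PIG(VI+) positive control.
#'
#' @param utility `[action, state]` utility matrix.
#' @param backup_kernel a `cmc_kernel` or `[a, s, s']` probability array.
#' @param gamma discount factor in (0, 1] (default 0.95).
#' @param horizon number of backups (default 10); 0 returns `utility`.
#' @return a matrix `[action, state]` of class `q_table` with attributes
#'   `gamma` and `horizon`.
#' @export
value_iterate <- function(utility, backup_kernel, gamma = 0.95, horizon = 10) {
  th <- if (inherits(backup_kernel, "cmc_kernel")) backup_kernel$theta else backup_kernel
  M <- nrow(utility); N <- ncol(utility)
  if (!identical(dim(th), c(M, N, N)))
    stop_invalid("backup kernel shape does not match the utility table")
  rs <- apply(th, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-9)) stop_invalid("backup kernel rows must sum to 1")
  if (horizon < 0) stop_invalid("horizon must be >= 0")
  q <- utility
  for (i in seq_len(horizon)) {
    vmax <- apply(q, 2, max)
    for (a in seq_len(M)) q[a, ] <- utility[a, ] + gamma * (th[a, , ] %*% vmax)
  }
  structure(q, gamma = gamma, horizon = horizon, class = c("q_table", "matrix", "array"))
}

#' Least-taken-action choice
#'
#' Picks the action performed least often in the current state, ties
#' uniform.
#'
#' @param action_counts integer matrix `[action, state]` of past choices.
#' @param s current state.
#' @return an action index.
#' @export
choose_lta <- function(action_counts, s) argmin_tie(action_counts[, s])

#' Counter-based choice
#'
#' Seeks a uniform state occupancy: picks the action minimizing the
#' model-expected visit count of the resulting state,
#' `argmin_a sum_s' theta_hat[a, s, s'] * state_counts[s']`, ties uniform.
#'
#' @param model a `posterior_model`.
#' @param state_counts numeric vector of past state-visit counts.
#' @param s current state.
#' @return an action index.
#' @export
choose_cb <- function(model, state_counts, s) {
  expected <- vapply(seq_len(model$n_actions),
                     function(a) sum(model$theta_hat[a, s, ] * state_counts),
                     numeric(1))
  argmin_tie(expected)
}

#' Q-learning-on-surprise strategy specification
#'
#' The PEIG(Q) agent keeps a model-free Q table initialized at 0; after
#' each real transition `(s, a, s')` the reward is the surprise (PEIG) of
#' the row update just performed, and
#' `q(a, s) <- (1 - eta) q(a, s) + eta (r + gamma max_a' q(a', s'))`.
#' Actions are epsilon-greedy on q.
#'
#' @param learning_rate eta in (0, 1] (default 0.1).
#' @param gamma discount factor (default 0.95).
#' @param epsilon exploration rate in \\[0, 1\\] (default 0.1).
#' @return a strategy specification usable by [run_exploration()].
#' @export
peig_q_agent <- function(learning_rate = 0.1, gamma = 0.95, epsilon = 0.1) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop_invalid("learning_rate must be in (0, 1]")
  if (epsilon < 0 || epsilon > 1) stop_invalid("epsilon must be in [0, 1]")
  list(name = "peig_q", learning_rate = learning_rate, gamma = gamma,
       epsilon = epsilon)
}

#' One PEIG(Q) table update
#'
#' Applies the Q-learning-on-surprise rule
#' `q(a, s) <- (1 - eta) q(a, s) + eta (r + gamma max_a' q(a', s'))` for one
#' observed transition.
#'
#' @param q `[action, state]` Q matrix.
#' @param a,s,s_next the transition taken.
#' @param reward the surprise (PEIG) of the model update, in bits.
#' @param learning_rate,gamma Q-learning hyperparameters.
#' @return the updated Q matrix.
#' @export
peig_q_update <- function(q, a, s, s_next, reward, learning_rate = 0.1,
                          gamma = 0.95) {
  q[a, s] <- (1 - learning_rate) * q[a, s] +
    learning_rate * (reward + gamma * max(q[, s_next]))
  q
}

#' Run one exploration trace
#'
#' Simulates an agent exploring `world` for `n_steps` steps: starting from
#' a uniformly random state, it repeatedly selects an action under the
#' strategy (teleporting first when unembodied), samples the transition
#' from the true kernel, records the observation in its Bayesian model, and
#' logs missing information before any observation and every `eval_every`
#' steps.
#'
#' @param world a `cmc_kernel`.
#' @param strategy a label from [exploration_strategies()] or a list
#'   `list(name = ..., gamma = ..., horizon = ..., ...)` overriding
#'   defaults (see [peig_q_agent()]).
#' @param n_steps number of steps (>= 0).
#' @param eval_every evaluation cadence in steps (default 10).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param prior optional prior override, `list(family = , alpha = )`;
#'   defaults to the prior matched to the world's generative class
#'   (1-2-3 worlds get the discrete support prior, everything else a flat
#'   Dirichlet).
#' @param s0 optional fixed starting state.
#' @return an `exploration_trace`: list with `states` (length
#'   `n_steps + 1`), `actions`, `eval_times`, `missing_info`,
#'   `strategy_name`, `seed`, and the final `model` (a `posterior_model`).
#' @examples
#' w <- sample_dense_world(5, 2)
#' tr <- run_exploration(w, "pig_greedy", n_steps = 50, seed = 1)
#' tail(tr$missing_info, 1) < tr$missing_info[1]
#' @export
run_exploration <- function(world, strategy = "random", n_steps,
                            eval_every = 10, seed = NULL, prior = NULL,
                            s0 = NULL) {
  spec <- as_strategy(strategy)
  if (n_steps < 0) stop_invalid("n_steps must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  N <- world$n_states; M <- world$n_actions
  if (is.null(prior)) prior <- matched_prior(world)
  if (is.null(prior$alpha)) prior$alpha <- 1
  if (!"alpha_tensor" %in% names(prior)) prior$alpha_tensor <- NULL
  prior_code <- if (prior$family == "onetwothree") 1L else 0L
  if (prior_code == 1L && M != 3L)
    stop_invalid("the onetwothree prior requires a 3-action world")
  if (is.null(s0)) s0 <- sample.int(N, 1L)

  flat <- as.numeric(aperm(world$theta, c(3, 2, 1)))
  alpha_flat <- if (!is.null(prior$alpha_tensor))
    as.numeric(aperm(prior$alpha_tensor, c(3, 2, 1))) else numeric(0)
  res <- explore_core(flat, N, M, as.integer(n_steps), as.integer(eval_every),
                      spec$code, UTILITY_CODES[[spec$utility]],
                      prior_code, prior$alpha, alpha_flat,
                      isTRUE(spec$vi_true_kernel), spec$gamma,
                      as.integer(spec$horizon),
                      spec$learning_rate, spec$epsilon, as.integer(s0 - 1L))

  model <- posterior_model(N, M, prior$family, prior$alpha,
                           alpha_tensor = prior$alpha_tensor)
  model$counts <- aperm(array(res$counts, c(N, N, M)), c(3, 2, 1))
  model$total <- as.integer(n_steps)
  model$theta_hat <- aperm(array(res$theta_hat, c(N, N, M)), c(3, 2, 1))

  structure(
    list(states = res$states, actions = res$actions, origins = res$origins,
         eval_times = res$eval_steps, missing_info = res$missing_info,
         strategy_name = spec$name, strategy = spec,
         world_class = world$class_label, seed = seed,
         n_steps = as.integer(n_steps), eval_every = as.integer(eval_every),
         prior = prior, model = model),
    class = "exploration_trace")
}

#' @export
print.exploration_trace <- function(x, ...) {
  cat(sprintf("<exploration_trace> %s on %s world: %d steps, I_M %.2f -> %.2f bits\n",
              x$strategy_name, x$world_class, x$n_steps,
              x$missing_info[1], x$missing_info[length(x$missing_info)]))
  invisible(x)
}

#' Export a trace to CSV / JSON
#'
#' Writes the per-step (step, state, action) table as CSV and, optionally,
#' a JSON summary holding the evaluation grid and missing-information
#' curve.
#'
#' @param trace an `exploration_trace`.
#' @param csv_path path for the step table (NULL to skip).
#' @param json_path path for the JSON summary (NULL to skip).
#' @return invisibly, the step table data frame.
#' @export
write_trace <- function(trace, csv_path = NULL, json_path = NULL) {
  steps <- data.frame(step = seq_len(trace$n_steps),
                      state = trace$states[-1],
                      action = trace$actions)
  if (!is.null(csv_path)) utils::write.csv(steps, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(strategy = trace$strategy_name, world_class = trace$world_class,
           seed = trace$seed, eval_times = trace$eval_times,
           missing_info = trace$missing_info),
      json_path, digits = NA, auto_unbox = TRUE)
  invisible(steps)
}

#' Export a utility table to CSV
#'
#' @param tab a `utility_table`.
#' @param path output path.
#' @return invisibly, the long-format data frame written.
#' @export
write_utility_csv <- function(tab, path) {
  df <- data.frame(action = as.vector(row(tab)), state = as.vector(col(tab)),
                   value = as.vector(tab),
                   utility_name = attr(tab, "utility_name"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
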