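# Hand-built fixture worlds and replay utilities used across test files.

# Deterministic N-cycle: action 1 advances s -> s + 1 (mod N); any extra
# actions stay put.
cycle_world <- function(n, m = 1) {
  th <- array(0, c(m, n, n))
  for (s in seq_len(n)) {
    th[1, s, s %% n + 1] <- 1
    if (m > 1) for (a in 2:m) th[a, s, s] <- 1
  }
  cmc_kernel(th)
}

# Two actions on N states: action a teleports deterministically to state
# targets[a] from everywhere.
teleport_world <- function(n, targets) {
  m <- length(targets)
  th <- array(0, c(m, n, n))
  for (a in seq_len(m)) th[a, , targets[a]] <- 1
  cmc_kernel(th)
}

# Seed a posterior model with `k` random observations.
random_model <- function(world, k, family = NULL, alpha = 1) {
  if (is.null(family))
    family <- if (identical(world$class_label, "onetwothree")) "onetwothree"
              else "dirichlet"
  m <- posterior_model(world$n_states, world$n_actions, family, alpha)
  for (i in seq_len(k)) {
    a <- sample.int(world$n_actions, 1)
    s <- sample.int(world$n_states, 1)
    m <- record_observation(m, a, s, step_cmc(world, s, a))
  }
  m
}

# Replay a compiled trace through the R-level model update path, returning
# the missing-information curve recomputed at the trace's eval times.
replay_missing_info <- function(world, trace) {
  m <- posterior_model(world$n_states, world$n_actions,
                       trace$prior$family, trace$prior$alpha,
                       alpha_tensor = trace$prior$alpha_tensor)
  out <- numeric(length(trace$eval_times))
  out[1] <- missing_information(world, m)
  j <- 2L
  for (t in seq_len(trace$n_steps)) {
    m <- record_observation(m, trace$actions[t], trace$origins[t],
                            trace$states[t + 1])
    if (j <= length(trace$eval_times) && trace$eval_times[j] == t) {
      out[j] <- missing_information(world, m)
      j <- j + 1L
    }
  }
  list(missing_info = out, model = m)
}

# Breadth-first reachability over the union (any action, positive
# probability) transition graph.
reachable_from <- function(world, start) {
  adj <- apply(world$theta, c(2, 3), max) > 0
  seen <- logical(world$n_states)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}
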