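#' Bayesian internal models of a CMC kernel
#'
#' An exploring agent summarizes its history as per-(action, origin, result)
#' transition counts and maintains the posterior-mean estimate
#' `theta_hat` of the world kernel under a conjugate prior.  Two prior
#' families are supported:
#'
#' * `"dirichlet"`: each row has an independent symmetric Dirichlet prior
#'   with concentration `alpha` (default 1, the flat prior matched to Dense
#'   Worlds; also the default approximation for Mazes).  The posterior mean
#'   of a row with counts `c` is `(c + alpha) / (sum(c) + N * alpha)`.
#' * `"onetwothree"`: the discrete prior matched to 1-2-3 Worlds -- action
#'   `a` is uniform on an unknown support of exactly `a` distinct states,
#'   the support itself uniform over all size-`a` subsets.  The posterior
#'   mean follows from support-counting symmetry (see
#'   [posterior_mean_123()]).
#'
#' Maze agents default to a structured asymmetric Dirichlet whose per-row
#' concentrations encode the grid geometry and absorbing-state identity
#' without revealing the wall layout (see [maze_prior_alpha()]); any
#' per-row concentration tensor can be supplied via `alpha_tensor`.
#'
#' @param n_states,n_actions dimensions of the modeled world.
#' @param family prior family, `"dirichlet"` or `"onetwothree"`.
#' @param alpha symmetric Dirichlet concentration (> 0; dirichlet family).
#' @param alpha_tensor optional `[a, s, s']` array of per-row Dirichlet
#'   concentrations (dirichlet family; overrides `alpha`).
#' @return an object of class `posterior_model`: list with `prior`
#'   (`family`, `alpha`, optional `alpha_tensor`), integer `counts` array
#'   `[a, s, s']`, `total` observation count, and the posterior-mean array
#'   `theta_hat`.
#' @examples
#' m <- posterior_model(4, 2)
#' m$theta_hat[1, 1, ]  # prior mean: uniform
#' m <- record_observation(m, 1, 1, 3)
#' m$theta_hat[1, 1, ]
#' @export
posterior_model <- function(n_states, n_actions,
                            family = c("dirichlet", "onetwothree"),
                            alpha = 1, alpha_tensor = NULL) {
  family <- match.arg(family)
  if (alpha <= 0) stop_invalid("alpha must be positive")
  if (family == "onetwothree" && n_actions != 3L)
    stop_invalid("the onetwothree prior requires exactly 3 actions")
  if (!is.null(alpha_tensor)) {
    if (family != "dirichlet")
      stop_invalid("alpha_tensor applies to the dirichlet family only")
    if (!identical(dim(alpha_tensor), as.integer(c(n_actions, n_states, n_states))))
      stop_invalid("alpha_tensor must be an [a, s, s'] array matching the model")
    if (any(alpha_tensor < 0) || any(apply(alpha_tensor, c(1, 2), sum) <= 0))
      stop_invalid("alpha_tensor rows must be non-negative with positive sums")
  }
  m <- structure(
    list(prior = list(family = family, alpha = alpha,
                      alpha_tensor = alpha_tensor),
         n_states = as.integer(n_states), n_actions = as.integer(n_actions),
         counts = array(0L, c(n_actions, n_states, n_states)),
         total = 0L,
         theta_hat = array(0, c(n_actions, n_states, n_states))),
    class = "posterior_model")
  for (a in seq_len(n_actions)) for (s in seq_len(n_states))
    m$theta_hat[a, s, ] <- posterior_row(m, a, s)
  m
}

# Prior matched to a world's generative class: the discrete support prior
# for 1-2-3 worlds, the structured geometry-aware Dirichlet for mazes, the
# flat Dirichlet otherwise.
#' @noRd
matched_prior <- function(world) {
  if (identical(world$class_label, "onetwothree"))
    list(family = "onetwothree", alpha = 1, alpha_tensor = NULL)
  else if (identical(world$class_label, "maze") && !is.null(world$layout))
    list(family = "dirichlet", alpha = 1,
         alpha_tensor = maze_prior_alpha(world$layout))
  else
    list(family = "dirichlet", alpha = 1, alpha_tensor = NULL)
}

#' @export
print.posterior_model <- function(x, ...) {
  cat(sprintf("<posterior_model> %s prior, %d states, %d actions, %d observations\n",
              x$prior$family, x$n_states, x$n_actions, x$total))
  invisible(x)
}

# Posterior-mean row for (a, s) from the model's counts.
#' @noRd
posterior_row <- function(model, a, s, extra = NULL) {
  cnt <- model$counts[a, s, ]
  if (!is.null(extra)) cnt[extra] <- cnt[extra] + 1L
  if (model$prior$family == "dirichlet") {
    al <- if (!is.null(model$prior$alpha_tensor))
      model$prior$alpha_tensor[a, s, ] else model$prior$alpha
    posterior_mean_dirichlet(cnt, al)
  } else {
    posterior_mean_123(a, which(cnt > 0L), model$n_states)
  }
}

#' Posterior mean of a Dirichlet-multinomial row
#'
#' For a transition row with Dirichlet(`alpha`) prior and observed outcome
#' counts `row_counts`, the posterior mean is
#' `(c_i + alpha_i) / (sum(c) + sum(alpha))`.  A scalar `alpha` gives the
#' symmetric prior; a vector gives an asymmetric (e.g. geometry-structured)
#' prior, where zero-concentration outcomes are excluded a priori.
#'
#' @param row_counts non-negative integer vector of outcome counts.
#' @param alpha concentration parameter: positive scalar, or non-negative
#'   vector of the same length with positive sum.
#' @return probability vector of the same length.
#' @examples
#' posterior_mean_dirichlet(c(1, 0), 1)  # 2/3, 1/3
#' @export
posterior_mean_dirichlet <- function(row_counts, alpha = 1) {
  if (any(alpha < 0) || sum(alpha) <= 0) stop_invalid("alpha must be positive")
  if (length(alpha) > 1 && length(alpha) != length(row_counts))
    stop_invalid("alpha must be scalar or match the row length")
  if (any(row_counts < 0)) stop_invalid("counts must be non-negative")
  al <- rep_len(alpha, length(row_counts))
  (row_counts + al) / (sum(row_counts) + sum(al))
}

#' Posterior mean of a 1-2-3 World row
#'
#' Under the matched discrete prior, action `a_label` is uniform on an
#' unknown support of exactly `a_label` distinct states, with the support
#' uniform over all size-`a_label` subsets of the `n_states` states.  All
#' supports containing the `k` observed outcome states are equally likely a
#' posteriori, so each observed state carries probability `1 / a`, and by
#' symmetry each unobserved state is a support member with probability
#' `(a - k) / (N - k)`, giving it probability `(a - k) / (a * (N - k))`.
#'
#' @param a_label action label in `{1, 2, 3}` (equals the support size).
#' @param observed_outcomes integer vector of states observed as outcomes
#'   (duplicates allowed; only distinct values matter).
#' @param n_states number of states N.
#' @return probability vector of length `n_states`.
#' @examples
#' posterior_mean_123(2, c(3), 10)      # state 3: 0.5, others 1/18
#' posterior_mean_123(2, c(3, 7), 10)   # support identified
#' @export
posterior_mean_123 <- function(a_label, observed_outcomes, n_states) {
  if (!a_label %in% 1:3) stop_invalid("a_label must be 1, 2 or 3")
  obs <- unique(as.integer(observed_outcomes))
  k <- length(obs)
  if (k > a_label)
    stop_invalid("inconsistent data: ", k,
                 " distinct outcomes observed for a size-", a_label, " support")
  p <- rep((a_label - k) / (a_label * (n_states - k)), n_states)
  p[obs] <- 1 / a_label
  p
}

#' Read and write model checkpoints as JSON
#'
#' Serializes a `posterior_model` (prior specification, counts, and the
#' posterior-mean kernel) to a plain JSON document at full double
#' precision, and restores it.
#'
#' @param model a `posterior_model`.
#' @param path file path.
#' @return `write_model` returns `path` invisibly; `read_model` the
#'   reconstructed `posterior_model`.
#' @export
write_model <- function(model, path) {
  M <- model$n_actions; N <- model$n_states
  nest <- function(x) lapply(seq_len(M), function(a)
    lapply(seq_len(N), function(s) x[a, s, ]))
  doc <- list(n_states = N, n_actions = M,
              family = model$prior$family, alpha = model$prior$alpha,
              total = model$total, counts = nest(model$counts),
              theta_hat = nest(model$theta_hat))
  if (!is.null(model$prior$alpha_tensor))
    doc$alpha_tensor <- nest(model$prior$alpha_tensor)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  M <- doc$n_actions; N <- doc$n_states
  unnest <- function(x, mode = "double") {
    arr <- array(vector(mode, 1), c(M, N, N))
    for (a in seq_len(M)) for (s in seq_len(N))
      arr[a, s, ] <- as.vector(unlist(x[[a]][[s]]), mode = mode)
    arr
  }
  at <- if (!is.null(doc$alpha_tensor)) unnest(doc$alpha_tensor)
  m <- posterior_model(N, M, doc$family, doc$alpha, alpha_tensor = at)
  m$counts <- unnest(doc$counts, "integer")
  m$total <- doc$total
  m$theta_hat <- unnest(doc$theta_hat)
  m
}

#' Record one observed transition
#'
#' Increments `counts[a, s, s_next]` and recomputes the posterior mean of
#' the single affected row; all other rows are untouched.
#'
#' @param model a `posterior_model`.
#' @param a action taken.
#' @param s originating state.
#' @param s_next observed resulting state.
#' @return the updated `posterior_model`.
#' @export
record_observation <- function(model, a, s, s_next) {
  N <- model$n_states; M <- model$n_actions
  if (a < 1 || a > M || s < 1 || s > N || s_next < 1 || s_next > N)
    stop_invalid("index out of range")
  model$counts[a, s, s_next] <- model$counts[a, s, s_next] + 1L
  model$total <- model$total + 1L
  model$theta_hat[a, s, ] <- posterior_row(model, a, s)
  model
}

#' Hypothetical one-observation row update
#'
#' Returns the posterior-mean row for `(a, s)` that *would* result from one
#' additional observation of outcome `s_star`, without mutating the model.
#' This is the hypothetical model entering the predicted information gain.
#'
#' @inheritParams record_observation
#' @param s_star hypothetical outcome state.
#' @return probability vector over resulting states.
#' @export
hypothetical_row <- function(model, a, s, s_star) {
  N <- model$n_states
  if (a < 1 || a > model$n_actions || s < 1 || s > N || s_star < 1 || s_star > N)
    stop_invalid("index out of range")
  posterior_row(model, a, s, extra = s_star)
}
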