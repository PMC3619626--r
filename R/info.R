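#' Kullback-Leibler divergence in bits
#'
#' `sum(p * log2(p / q))` with the convention `0 * log(0 / .) = 0`.  If some
#' outcome has `p > 0` but `q = 0` the divergence is infinite and `Inf` is
#' returned (a flag the caller decides how to treat, not an error): discrete
#' 1-2-3 posteriors legitimately place zero mass on excluded outcomes.
#'
#' @param p,q probability vectors of equal length (`p` the reference, `q`
#'   the approximation).
#' @return divergence in bits, `>= 0`, possibly `Inf`.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))      # 1 bit
#' kl_divergence(c(0.75, 0.25), c(0.5, 0.5))
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop_invalid("p and q must have equal length")
  i <- p > 0
  if (any(q[i] == 0)) return(Inf)
  sum(p[i] * log2s(p[i] / q[i]))
}

#' Missing information of an internal model
#'
#' The learning objective: the unweighted sum over all (state, action) rows
#' of the KL divergence of the model row from the true row,
#' `I_M = sum_{s,a} D_KL(theta[a,s,] || theta_hat[a,s,])`, in bits.
#'
#' @param world a `cmc_kernel` (the truth).
#' @param theta_hat model kernel: a probability array of the same shape, or
#'   a `posterior_model` (its `$theta_hat` is used).
#' @return missing information in bits (possibly `Inf`).
#' @export
missing_information <- function(world, theta_hat) {
  if (inherits(theta_hat, "posterior_model")) theta_hat <- theta_hat$theta_hat
  if (!identical(dim(world$theta), dim(theta_hat)))
    stop_invalid("shape mismatch between world and model")
  total <- 0
  for (a in seq_len(world$n_actions))
    for (s in seq_len(world$n_states))
      total <- total + kl_divergence(world$theta[a, s, ], theta_hat[a, s, ])
  total
}

#' Realized information gain of one model update
#'
#' The decrease in missing information contributed by one row when the
#' model row moves from `old_row` to `new_row`:
#' `I_G = sum_{s'} world_row[s'] * log2(new_row[s'] / old_row[s'])`.  It can
#' be negative for an unlucky single observation.
#'
#' @param world_row true transition row.
#' @param old_row,new_row model row before and after the update.
#' @return information gain in bits (possibly `+-Inf`).
#' @export
information_gain <- function(world_row, old_row, new_row) {
  n <- length(world_row)
  if (length(old_row) != n || length(new_row) != n)
    stop_invalid("rows must have equal length")
  i <- world_row > 0
  if (any(new_row[i] == 0)) return(-Inf)
  if (any(old_row[i] == 0)) return(Inf)
  sum(world_row[i] * log2s(new_row[i] / old_row[i]))
}

# Generic one-step predicted change of a model row: expectation over the
# hypothetical outcome s* (under the current model) of `dist_fn(hyp, cur)`.
#' @noRd
predicted_change <- function(model, a, s, dist_fn) {
  cur <- model$theta_hat[a, s, ]
  total <- 0
  for (s_star in seq_len(model$n_states)) {
    w <- cur[s_star]
    if (w <= 0) next                      # impossible outcomes contribute 0
    hyp <- posterior_row(model, a, s, extra = s_star)
    total <- total + w * dist_fn(hyp, cur)
  }
  total
}

#' Predicted information gain (PIG)
#'
#' The posterior-expected information gain of one more observation of row
#' `(a, s)`:
#' `PIG(a, s) = sum_{s*} theta_hat[a,s,s*] * D_KL(hyp(s*) || theta_hat[a,s,])`,
#' where `hyp(s*)` is the hypothetical row after additionally observing
#' outcome `s*`.  PIG equals the expected decrease in missing information
#' when the prior is well specified, and is always non-negative.
#'
#' @param model a `posterior_model`.
#' @param a,s action and state indexing the row.
#' @return predicted information gain in bits.
#' @examples
#' m <- posterior_model(2, 1)
#' predicted_information_gain(m, 1, 1)  # 0.0817 bits
#' @export
predicted_information_gain <- function(model, a, s) {
  predicted_change(model, a, s, kl_divergence)
}

#' Predicted mode change (PMC)
#'
#' The expected increase of the model row's modal probability after one
#' more observation:
#' `PMC(a, s) = sum_{s*} theta_hat[a,s,s*] * (max(hyp(s*)) - max(theta_hat[a,s,]))`.
#'
#' @inheritParams predicted_information_gain
#' @return predicted mode change (probability units).
#' @export
predicted_mode_change <- function(model, a, s) {
  predicted_change(model, a, s, function(hyp, cur) max(hyp) - max(cur))
}

#' Predicted L1 change (PLC)
#'
#' The expected average L1 distance between the current and updated model
#' rows:
#' `PLC(a, s) = sum_{s*} theta_hat[a,s,s*] * mean(abs(hyp(s*) - theta_hat[a,s,]))`.
#'
#' @inheritParams predicted_information_gain
#' @return predicted L1 change.
#' @export
predicted_L1_change <- function(model, a, s) {
  predicted_change(model, a, s, function(hyp, cur) mean(abs(hyp - cur)))
}

#' Posterior expected information gain (PEIG, "surprise")
#'
#' The realized surprise of an update already made: the KL divergence of
#' the new model row from the pre-update row,
#' `PEIG = D_KL(new_row || old_row)`.  Unlike PIG it looks backward at the
#' change just observed rather than forward at expected change.
#'
#' @param old_row model row before the update.
#' @param new_row model row after the update.
#' @return surprise in bits, `>= 0`.
#' @export
posterior_expected_information_gain <- function(old_row, new_row) {
  kl_divergence(new_row, old_row)
}

#' Tabulate a one-step utility over all (action, state) pairs
#'
#' @param model a `posterior_model`.
#' @param utility `"pig"`, `"pmc"` or `"plc"`.
#' @return a `utility_table`: numeric matrix `[action, state]` with
#'   attribute `utility_name`.
#' @export
utility_table <- function(model, utility = c("pig", "pmc", "plc")) {
  utility <- match.arg(utility)
  fn <- switch(utility,
               pig = predicted_information_gain,
               pmc = predicted_mode_change,
               plc = predicted_L1_change)
  tab <- matrix(0, model$n_actions, model$n_states)
  for (a in seq_len(model$n_actions))
    for (s in seq_len(model$n_states))
      tab[a, s] <- fn(model, a, s)
  structure(tab, utility_name = utility, class = c("utility_table", "matrix", "array"))
}
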