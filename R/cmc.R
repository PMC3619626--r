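#' Controllable Markov Chain kernels
#'
#' A Controllable Markov Chain (CMC) is a Markov chain augmented with a
#' control variable: in each state `s` the agent picks an action `a`, and the
#' next state is drawn from the transition distribution `theta[a, s, ]`.  A
#' CMC is an MDP without a reward structure; here it serves as the "world"
#' an exploring agent has to learn.
#'
#' The kernel is stored as a 3-d probability array `theta` with dimensions
#' `c(n_actions, n_states, n_states)` indexed `[action, origin, result]`.
#' Every row `theta[a, s, ]` lies on the probability simplex.
#'
#' @param theta numeric array, dim `c(n_actions, n_states, n_states)`, rows
#'   summing to 1.
#' @param class_label optional character tag recording the generative class
#'   (`"dense"`, `"maze"`, `"onetwothree"`, or `"custom"`).
#' @param layout optional `maze_layout` object (maze worlds only).
#' @param supports optional target-support list (1-2-3 worlds only).
#' @return An object of class `cmc_kernel`: a list with elements `n_states`,
#'   `n_actions`, `theta`, `class_label`, and optionally `layout`/`supports`.
#' @examples
#' th <- array(0, c(1, 2, 2))
#' th[1, 1, ] <- c(0.5, 0.5); th[1, 2, ] <- c(1, 0)
#' w <- cmc_kernel(th)
#' w$n_states
#' @export
cmc_kernel <- function(theta, class_label = "custom", layout = NULL,
                       supports = NULL) {
  d <- dim(theta)
  if (is.null(d) || length(d) != 3L || d[2] != d[3])
    stop_invalid("`theta` must be an [action, origin, result] array with square state dimensions")
  obj <- structure(
    list(n_states = d[2], n_actions = d[1], theta = theta,
         class_label = class_label, layout = layout, supports = supports),
    class = "cmc_kernel")
  validate_cmc_kernel(obj)
  obj
}

#' Validate a CMC kernel
#'
#' Checks the simplex invariants: non-negative entries, rows summing to 1
#' within `tol`, at least two states and one action.
#'
#' @param kernel a `cmc_kernel`.
#' @param tol row-sum tolerance (default `1e-9`).
#' @return the kernel, invisibly; errors if invalid.
#' @export
validate_cmc_kernel <- function(kernel, tol = 1e-9) {
  th <- kernel$theta
  if (kernel$n_states < 2L) stop_invalid("a CMC needs at least 2 states")
  if (kernel$n_actions < 1L) stop_invalid("a CMC needs at least 1 action")
  if (any(th < 0)) stop_invalid("negative transition probabilities")
  rs <- apply(th, c(1, 2), sum)
  if (any(abs(rs - 1) > tol))
    stop_invalid("transition rows must sum to 1 (max deviation ",
                 format(max(abs(rs - 1))), ")")
  invisible(kernel)
}

#' @export
print.cmc_kernel <- function(x, ...) {
  cat(sprintf("<cmc_kernel> %s world: %d states, %d actions\n",
              x$class_label, x$n_states, x$n_actions))
  invisible(x)
}

#' Simulate one state transition
#'
#' Draws the next state from `theta[a, s, ]` of the world kernel.
#'
#' @param kernel a `cmc_kernel`.
#' @param s current state (1-based index).
#' @param a action (1-based index).
#' @return the resulting state index.
#' @examples
#' w <- sample_dense_world(4, 2)
#' step_cmc(w, 1, 1)
#' @export
step_cmc <- function(kernel, s, a) {
  if (s < 1L || s > kernel$n_states) stop_invalid("state index out of range")
  if (a < 1L || a > kernel$n_actions) stop_invalid("action index out of range")
  p <- kernel$theta[a, s, ]
  sample.int(kernel$n_states, 1L, prob = p)
}

#' Read and write CMC kernels as JSON
#'
#' Kernels (with any maze layout or 1-2-3 support annotation) serialize to a
#' plain JSON document holding `n_states`, `n_actions` and the nested
#' `theta` lists at full double precision, so a write-then-read round trip
#' reproduces `theta` bit-exactly.
#'
#' @param kernel a `cmc_kernel`.
#' @param path file path.
#' @return `write_cmc` returns `path` invisibly; `read_cmc` returns the
#'   reconstructed `cmc_kernel`.
#' @export
write_cmc <- function(kernel, path) {
  doc <- list(
    n_states = kernel$n_states,
    n_actions = kernel$n_actions,
    class_label = kernel$class_label,
    # nested [action][origin][result] lists
    theta = lapply(seq_len(kernel$n_actions), function(a)
      lapply(seq_len(kernel$n_states), function(s) kernel$theta[a, s, ]))
  )
  if (!is.null(kernel$layout)) {
    lay <- kernel$layout
    doc$layout <- list(
      grid_side = lay$grid_side,
      open = lay$open, transporter = lay$transporter,
      absorbing_state = lay$absorbing_state)
  }
  if (!is.null(kernel$supports)) doc$supports <- kernel$supports
  # 17 significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cmc
#' @export
read_cmc <- function(path) {
  doc <- jsonlite::read_json(path)        # unsimplified: shapes stay explicit
  M <- doc$n_actions; N <- doc$n_states
  theta <- array(0, c(M, N, N))
  for (a in seq_len(M)) for (s in seq_len(N))
    theta[a, s, ] <- as.numeric(unlist(doc$theta[[a]][[s]]))
  layout <- NULL
  if (!is.null(doc$layout)) {
    as_mat <- function(x)                 # matrices serialize row-wise
      matrix(as.logical(unlist(x)), nrow = length(x), byrow = TRUE)
    layout <- structure(
      list(grid_side = doc$layout$grid_side,
           open = as_mat(doc$layout$open),
           transporter = as_mat(doc$layout$transporter),
           absorbing_state = doc$layout$absorbing_state),
      class = "maze_layout")
    layout$wall_segments <- wall_segments(layout)
    layout$transporter_segments <- transporter_segments(layout)
  }
  supports <- NULL
  if (!is.null(doc$supports)) {
    supports <- lapply(doc$supports, function(by_state)
      lapply(by_state, function(v) as.integer(unlist(v))))
  }
  cmc_kernel(theta, class_label = doc$class_label, layout = layout,
             supports = supports)
}
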