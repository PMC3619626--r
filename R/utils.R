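# Internal numerical helpers shared across modules.

LOG2E <- 1 / log(2)

#' @noRd
log2s <- function(x) log(x) * LOG2E

# Draw one row from a Dirichlet distribution with concentration `alpha`
# (vector or scalar recycled to length n).
#' @noRd
rdirichlet_row <- function(n, alpha) {
  g <- stats::rgamma(n, shape = rep_len(alpha, n), rate = 1)
  # a zero draw is astronomically unlikely for alpha >= 1 but guard anyway
  while (sum(g) == 0) g <- stats::rgamma(n, shape = rep_len(alpha, n), rate = 1)
  g / sum(g)
}

# Shannon entropy in bits of a probability vector (0 log 0 := 0).
#' @noRd
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2s(p))
}

# Uniform-random tie-breaking argmax/argmin over a vector.
#' @noRd
argmax_tie <- function(x) {
  i <- which(x == max(x))
  if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
}

#' @noRd
argmin_tie <- function(x) argmax_tie(-x)

# Trapezoidal area under a curve sampled at ordered abscissae x.
#' @noRd
trapezoid_auc <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' @noRd
stop_invalid <- function(...) stop(..., call. = FALSE)
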