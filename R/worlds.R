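#' Generate a Dense World
#'
#' Dense Worlds are maximally unstructured CMCs: every transition row
#' `theta[a, s, ]` is drawn independently from the flat Dirichlet (all
#' concentration parameters 1), i.e. uniformly on the `(N-1)`-simplex.
#' Defaults give the canonical 10-state, 4-action configuration.
#'
#' @param n_states number of states (N >= 2).
#' @param n_actions number of actions (M >= 1).
#' @return a `cmc_kernel` with `class_label = "dense"`.
#' @examples
#' w <- sample_dense_world()
#' dim(w$theta)
#' @export
sample_dense_world <- function(n_states = 10, n_actions = 4) {
  if (n_states < 2) stop_invalid("n_states must be >= 2")
  if (n_actions < 1) stop_invalid("n_actions must be >= 1")
  theta <- array(0, c(n_actions, n_states, n_states))
  for (a in seq_len(n_actions))
    for (s in seq_len(n_states))
      theta[a, s, ] <- rdirichlet_row(n_states, 1)
  cmc_kernel(theta, class_label = "dense")
}

# ---- maze machinery ---------------------------------------------------------

# Directions: 1 = North, 2 = East, 3 = South, 4 = West (row-major grid).
DIR_OPP <- c(3L, 4L, 1L, 2L)

#' @noRd
maze_neighbor <- function(cell, d, g) {
  r <- (cell - 1L) %/% g
  c <- (cell - 1L) %% g
  switch(d,
         if (r == 0L) 0L else cell - g,        # N
         if (c == g - 1L) 0L else cell + 1L,   # E
         if (r == g - 1L) 0L else cell + g,    # S
         if (c == 0L) 0L else cell - 1L)       # W
}

# Wilson's loop-erased random-walk algorithm: a uniformly random spanning
# tree of the g x g grid graph, returned as a 2-column matrix of open edges.
#' @noRd
wilson_spanning_tree <- function(g) {
  n <- g * g
  nbrs <- lapply(seq_len(n), function(cell) {
    nb <- vapply(1:4, function(d) maze_neighbor(cell, d, g), integer(1))
    nb[nb > 0L]
  })
  in_tree <- logical(n)
  in_tree[sample.int(n, 1L)] <- TRUE
  nxt <- integer(n)
  edges <- matrix(integer(0), ncol = 2)
  for (start in sample.int(n)) {
    if (in_tree[start]) next
    u <- start
    while (!in_tree[u]) {              # random walk, implicit loop erasure
      nb <- nbrs[[u]]
      nxt[u] <- nb[sample.int(length(nb), 1L)]
      u <- nxt[u]
    }
    u <- start
    while (!in_tree[u]) {
      in_tree[u] <- TRUE
      edges <- rbind(edges, c(u, nxt[u]))
      u <- nxt[u]
    }
  }
  edges
}

# Canonical wall segments of a layout: each physical wall once.  Interior
# segments are identified by their North/West-side cell with dir E or S;
# boundary segments by the inside cell.
#' @noRd
wall_segments <- function(layout) {
  g <- layout$grid_side
  segs <- NULL
  for (cell in seq_len(g * g)) for (d in 1:4) {
    nb <- maze_neighbor(cell, d, g)
    if (nb == 0L) {
      segs <- rbind(segs, c(cell, d))                 # boundary wall
    } else if (d %in% c(2L, 3L) && !layout$open[cell, d]) {
      segs <- rbind(segs, c(cell, d))                 # closed interior wall
    }
  }
  segs <- as.data.frame(segs)
  names(segs) <- c("cell", "dir")
  segs
}

#' @noRd
transporter_segments <- function(layout) {
  segs <- wall_segments(layout)
  keep <- mapply(function(cell, d) layout$transporter[cell, d],
                 segs$cell, segs$dir)
  segs[keep, , drop = FALSE]
}

#' Generate a maze layout
#'
#' Rooms form a `grid_side` x `grid_side` grid.  Interior passages are the
#' edges of a uniformly random spanning tree (Wilson's algorithm) plus a
#' fraction `open_fraction` of the remaining interior walls, so that rooms
#' typically have several exits while the room graph stays connected.  All
#' boundary edges are walls.  `n_transporters` wall segments (boundary or
#' interior) are then marked as transporters leading to a uniformly chosen
#' absorbing room; translating "into" a transporter wall from either side
#' drops the agent into the absorbing state, from which no action escapes.
#'
#' @param grid_side side length of the room grid (default 6).
#' @param n_transporters number of transporter wall segments (default 30).
#' @param open_fraction fraction of the non-tree interior walls that are
#'   additionally opened (default 0.5).
#' @return a `maze_layout`: list with `grid_side`, logical `open` and
#'   `transporter` matrices (`N x 4`, directions N/E/S/W), the
#'   `absorbing_state`, and canonical `wall_segments` /
#'   `transporter_segments` data frames.
#' @export
sample_maze_layout <- function(grid_side = 6, n_transporters = 30,
                               open_fraction = 0.5) {
  g <- as.integer(grid_side)
  if (g < 2) stop_invalid("grid_side must be >= 2")
  n <- g * g
  open <- matrix(FALSE, n, 4)
  open_edge <- function(u, v) {
    for (d in 1:4) if (maze_neighbor(u, d, g) == v) {
      open[u, d] <<- TRUE
      open[v, DIR_OPP[d]] <<- TRUE
    }
  }
  tree <- wilson_spanning_tree(g)
  for (i in seq_len(nrow(tree))) open_edge(tree[i, 1], tree[i, 2])
  # open a fraction of the remaining interior walls
  closed <- NULL
  for (cell in seq_len(n)) for (d in c(2L, 3L)) {
    nb <- maze_neighbor(cell, d, g)
    if (nb > 0L && !open[cell, d]) closed <- rbind(closed, c(cell, nb))
  }
  if (!is.null(closed) && open_fraction > 0) {
    k <- floor(open_fraction * nrow(closed))
    if (k > 0) {
      pick <- sample.int(nrow(closed), k)
      for (i in pick) open_edge(closed[i, 1], closed[i, 2])
    }
  }
  layout <- structure(
    list(grid_side = g, open = open,
         transporter = matrix(FALSE, n, 4),
         absorbing_state = sample.int(n, 1L)),
    class = "maze_layout")
  segs <- wall_segments(layout)
  if (n_transporters > nrow(segs))
    stop_invalid("n_transporters (", n_transporters,
                 ") exceeds the number of wall segments (", nrow(segs), ")")
  pick <- segs[sample.int(nrow(segs), n_transporters), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    cell <- pick$cell[i]; d <- pick$dir[i]
    layout$transporter[cell, d] <- TRUE
    nb <- maze_neighbor(cell, d, g)
    if (nb > 0L) layout$transporter[nb, DIR_OPP[d]] <- TRUE
  }
  layout$wall_segments <- segs
  layout$transporter_segments <- transporter_segments(layout)
  layout
}

#' Build a maze transition kernel from a layout
#'
#' Translations are noisy: for each (state, intended direction) a 4-vector
#' of direction weights is drawn from a Dirichlet with concentration
#' `noise_concentration` on the intended direction and 1 on the other three,
#' so most probability mass follows the intended direction.  Each
#' direction's mass is then mapped through the layout: through an open edge
#' to the adjacent room, into a plain wall back to the same room, into a
#' transporter wall to the absorbing state.  The absorbing state self-loops
#' with probability 1 under every action.
#'
#' @param layout a `maze_layout`.
#' @param noise_concentration Dirichlet concentration on the intended
#'   direction (default 20; the limit `Inf` gives deterministic intended
#'   translations).
#' @return a `cmc_kernel` with `class_label = "maze"` and the layout
#'   attached.
#' @export
maze_kernel_from_layout <- function(layout, noise_concentration = 20) {
  g <- layout$grid_side
  n <- g * g
  theta <- array(0, c(4, n, n))
  for (s in seq_len(n)) {
    if (s == layout$absorbing_state) {
      theta[, s, s] <- 1
      next
    }
    for (a in 1:4) {
      if (is.finite(noise_concentration)) {
        conc <- c(1, 1, 1, 1)
        conc[a] <- noise_concentration
        w <- rdirichlet_row(4, conc)
      } else {
        w <- numeric(4); w[a] <- 1
      }
      for (d in 1:4) {
        nb <- maze_neighbor(s, d, g)
        target <- if (nb > 0L && layout$open[s, d]) nb
                  else if (layout$transporter[s, d]) layout$absorbing_state
                  else s
        theta[a, s, target] <- theta[a, s, target] + w[d]
      }
    }
  }
  cmc_kernel(theta, class_label = "maze", layout = layout)
}

#' Generate a Maze world
#'
#' Convenience wrapper: samples a layout with [sample_maze_layout()] and
#' realizes its noisy translation kernel with [maze_kernel_from_layout()].
#' Defaults give the canonical 36-room maze with 30 transporters.
#'
#' @inheritParams sample_maze_layout
#' @inheritParams maze_kernel_from_layout
#' @return a `cmc_kernel` (`class_label = "maze"`) with `$layout` attached.
#' @export
sample_maze_world <- function(grid_side = 6, n_transporters = 30,
                              noise_concentration = 20, open_fraction = 0.5) {
  layout <- sample_maze_layout(grid_side, n_transporters, open_fraction)
  maze_kernel_from_layout(layout, noise_concentration)
}

#' Structured prior concentrations for maze agents
#'
#' The conjugate prior matched (in structure) to the maze generative
#' process: the agent knows the grid geometry, which room is absorbing, the
#' translation-noise law, and the generator's wall statistics -- but not the
#' actual wall layout.  Each non-absorbing row `(a, s)` gets an asymmetric
#' Dirichlet whose mean is the marginal outcome distribution implied by
#' those constants: direction `d` carries expected noise mass
#' `conc_d / sum(conc)` (concentration `noise_concentration` on the
#' intended direction, 1 elsewhere), which splits into the adjacent room
#' (expected open-edge probability), the room itself (plain wall) or the
#' absorbing state (transporter wall), using the generator's expected
#' open-edge fraction and transporter-per-wall fraction.  Rows of the
#' absorbing state are known self-loops (a near-point concentration).
#'
#' The total concentration per row is `strength` pseudo-observations, so
#' the structural knowledge is weak and data quickly dominate.
#'
#' @param layout a `maze_layout` (only its grid size and absorbing room are
#'   used).
#' @param strength total prior concentration per row (default 1).
#' @param noise_concentration intended-direction concentration of the
#'   generator (default 20).
#' @param open_fraction generator's opening fraction for non-tree interior
#'   walls (default 0.5).
#' @param n_transporters generator's transporter count (default 30).
#' @return concentration array `[action, state, state]` for
#'   [posterior_model()] / [run_exploration()].
#' @export
maze_prior_alpha <- function(layout, strength = 1, noise_concentration = 20,
                             open_fraction = 0.5, n_transporters = 30) {
  g <- layout$grid_side
  n <- g * g
  # generator statistics, derived from its construction counts
  interior_edges <- 2 * g * (g - 1)
  tree_edges <- n - 1
  extra_open <- floor(open_fraction * (interior_edges - tree_edges))
  p_open <- (tree_edges + extra_open) / interior_edges
  n_walls <- (interior_edges - tree_edges - extra_open) + 4 * g
  p_tp <- min(n_transporters / n_walls, 1)
  conc <- function(a) {
    cv <- c(1, 1, 1, 1); cv[a] <- noise_concentration; cv / sum(cv)
  }
  ab <- layout$absorbing_state
  alpha <- array(0, c(4, n, n))
  for (s in seq_len(n)) {
    if (s == ab) {
      alpha[, s, s] <- 1e9              # known self-loop
      next
    }
    for (a in 1:4) {
      m <- conc(a)
      q <- numeric(n)
      for (d in 1:4) {
        nb <- maze_neighbor(s, d, g)
        if (nb > 0L) {
          q[nb] <- q[nb] + m[d] * p_open
          q[ab] <- q[ab] + m[d] * (1 - p_open) * p_tp
          q[s] <- q[s] + m[d] * (1 - p_open) * (1 - p_tp)
        } else {
          q[ab] <- q[ab] + m[d] * p_tp
          q[s] <- q[s] + m[d] * (1 - p_tp)
        }
      }
      alpha[a, s, ] <- strength * q
    }
  }
  alpha
}

#' Generate a 1-2-3 World
#'
#' 1-2-3 Worlds have three actions with discrete uniform supports: action
#' `a` (a = 1, 2, 3) moves the agent uniformly to one of `a` fixed target
#' states.  For every (action, state) pair the targets are a uniformly
#' random subset of `a` distinct states, drawn independently.
#'
#' @param n_states number of states (N >= 3, default 10).
#' @return a `cmc_kernel` with `class_label = "onetwothree"` and
#'   `$supports[[a]][[s]]`, the sorted integer target set of size `a`.
#' @export
sample_onetwothree_world <- function(n_states = 10) {
  if (n_states < 3) stop_invalid("n_states must be >= 3 for a 1-2-3 world")
  theta <- array(0, c(3, n_states, n_states))
  supports <- lapply(1:3, function(a) vector("list", n_states))
  for (a in 1:3) for (s in seq_len(n_states)) {
    targets <- sort(sample.int(n_states, a))
    supports[[a]][[s]] <- targets
    theta[a, s, targets] <- 1 / a
  }
  cmc_kernel(theta, class_label = "onetwothree", supports = supports)
}
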