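test_that("Dirichlet posterior means follow the conjugate formula", {
  expect_equal(posterior_mean_dirichlet(rep(0, 10), 1), rep(0.1, 10))
  expect_equal(posterior_mean_dirichlet(c(1, 0), 1), c(2 / 3, 1 / 3))
  # three observations of outcome 1 and one of outcome 2, alpha = 1, N = 4
  expect_equal(posterior_mean_dirichlet(c(3, 1, 0, 0), 1),
               c(0.5, 0.25, 0.125, 0.125))
  # consistency: frequencies dominate as counts grow
  freq <- c(0.2, 0.5, 0.3)
  expect_equal(posterior_mean_dirichlet(freq * 1e6, 1), freq, tolerance = 1e-5)
  expect_error(posterior_mean_dirichlet(c(-1, 2), 1), "non-negative")
  expect_error(posterior_mean_dirichlet(c(1, 2), 0), "positive")
})

test_that("record_observation updates exactly one row and the total", {
  m <- posterior_model(4, 2)
  before <- m$theta_hat
  for (i in 1:3) m <- record_observation(m, 1, 2, 1)
  m <- record_observation(m, 1, 2, 2)
  expect_equal(m$theta_hat[1, 2, ], c(0.5, 0.25, 0.125, 0.125))
  expect_equal(m$total, 4L)
  # every other row is untouched
  for (a in 1:2) for (s in 1:4)
    if (!(a == 1 && s == 2))
      expect_identical(m$theta_hat[a, s, ], before[a, s, ])
  expect_error(record_observation(m, 3, 1, 1), "out of range")
})

test_that("1-2-3 posterior means match the support-symmetry formula", {
  expect_equal(posterior_mean_123(2, integer(0), 10), rep(0.1, 10))
  p <- posterior_mean_123(2, 3, 10)
  expect_equal(p[3], 0.5)
  expect_equal(p[-3], rep(1 / 18, 9))
  p2 <- posterior_mean_123(2, c(3, 7), 10)
  expect_equal(p2[c(3, 7)], c(0.5, 0.5))
  expect_equal(sum(p2), 1)
  expect_true(all(p2[-c(3, 7)] == 0))
  expect_error(posterior_mean_123(1, c(2, 5), 10), "inconsistent")
})

test_that("1-2-3 posterior means agree with exhaustive support enumeration", {
  # brute force: average the uniform-on-support rows of every support
  # consistent with the observed outcomes (all consistent supports are
  # equally likely: the likelihood (1/a)^n is support-independent)
  oracle <- function(a, obs, n) {
    sup <- utils::combn(n, a)
    keep <- apply(sup, 2, function(col) all(obs %in% col))
    rows <- apply(sup[, keep, drop = FALSE], 2, function(col) {
      r <- numeric(n); r[col] <- 1 / a; r
    })
    rowMeans(rows)
  }
  set.seed(9)
  for (a in 1:3) {
    for (k in 0:a) {
      for (n in c(5, 10)) {
        obs <- if (k > 0) sample.int(n, k) else integer(0)
        expect_equal(posterior_mean_123(a, obs, n), oracle(a, obs, n),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("hypothetical rows preview the update without mutating the model", {
  m <- posterior_model(2, 1)
  expect_equal(hypothetical_row(m, 1, 1, 1), c(2 / 3, 1 / 3))
  expect_equal(m$theta_hat[1, 1, ], c(0.5, 0.5))   # untouched
  # hypothetical equals the row after actually recording the observation
  set.seed(4)
  w <- sample_dense_world(6, 2)
  m <- random_model(w, 25)
  for (i in 1:10) {
    a <- sample.int(2, 1); s <- sample.int(6, 1); st <- sample.int(6, 1)
    expect_equal(hypothetical_row(m, a, s, st),
                 record_observation(m, a, s, st)$theta_hat[a, s, ])
  }
  # a fully-learned deterministic 1-2-3 action cannot change
  m3 <- posterior_model(10, 3, "onetwothree")
  m3 <- record_observation(m3, 1, 4, 8)
  expect_equal(hypothetical_row(m3, 1, 4, 8), m3$theta_hat[1, 4, ])
})

test_that("vector-alpha Dirichlet rows generalize the symmetric formula", {
  expect_equal(posterior_mean_dirichlet(c(2, 0, 1), c(1, 1, 1)),
               posterior_mean_dirichlet(c(2, 0, 1), 1))
  al <- c(0.5, 0, 1.5)
  expect_equal(posterior_mean_dirichlet(c(0, 0, 0), al), al / sum(al))
  expect_equal(posterior_mean_dirichlet(c(1, 1, 0), al),
               (c(1, 1, 0) + al) / (2 + sum(al)))
  expect_error(posterior_mean_dirichlet(c(1, 1), c(0, 0)), "positive")
})

test_that("the structured maze prior encodes geometry without the layout", {
  set.seed(20)
  lay <- sample_maze_layout()
  al <- maze_prior_alpha(lay)
  ab <- lay$absorbing_state
  g <- lay$grid_side
  for (s in setdiff(seq_len(g * g), ab)) for (a in 1:4) {
    row <- al[a, s, ]
    # one pseudo-observation per row
    expect_equal(sum(row), 1, tolerance = 1e-12)
    # support: grid neighbors, the room itself, and the absorbing state only
    nbrs <- Filter(function(x) x > 0,
                   vapply(1:4, function(d)
                     pigexplore:::maze_neighbor(s, d, g), integer(1)))
    expect_true(all(which(row > 0) %in% c(nbrs, s, ab)))
    # the intended direction dominates when it has an in-grid neighbor
    nb_int <- pigexplore:::maze_neighbor(s, a, g)
    if (nb_int > 0 && !nb_int %in% c(s, ab))
      expect_equal(which.max(row), nb_int)
  }
  # absorbing rows are known self-loops
  m <- posterior_model(36, 4, alpha_tensor = al)
  expect_equal(m$theta_hat[1, ab, ab], 1, tolerance = 1e-9)
  expect_equal(predicted_information_gain(m, 1, ab), 0, tolerance = 1e-9)
  # the prior model's rows are supported wherever true maze rows are
  w <- maze_kernel_from_layout(lay, 20)
  expect_true(is.finite(missing_information(w, m)))
})

test_that("model checkpoints round-trip through JSON", {
  set.seed(23)
  w <- sample_maze_world()
  tr <- run_exploration(w, "pig_vi", 40, seed = 2)
  path <- tempfile(fileext = ".json")
  write_model(tr$model, path)
  back <- read_model(path)
  expect_identical(back$counts, tr$model$counts)
  expect_identical(back$theta_hat, tr$model$theta_hat)
  expect_identical(back$prior$alpha_tensor, tr$model$prior$alpha_tensor)
  expect_equal(back$total, 40)
  unlink(path)
})

test_that("posterior means converge to the true row with data (consistency)", {
  set.seed(14)
  w <- sample_dense_world(5, 1)
  m <- posterior_model(5, 1)
  for (i in 1:4000) m <- record_observation(m, 1, 2, step_cmc(w, 2, 1))
  expect_lt(max(abs(m$theta_hat[1, 2, ] - w$theta[1, 2, ])), 0.05)
  expect_lt(kl_divergence(w$theta[1, 2, ], m$theta_hat[1, 2, ]), 0.01)
})
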