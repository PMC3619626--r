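test_that("choose_random is uniform over actions and state-independent", {
  set.seed(1)
  draws <- replicate(10000, choose_random(4))
  freq <- tabulate(draws, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))
  expect_true(all(replicate(10, choose_random(1)) == 1))
})

test_that("choose_unembodied returns the global PIG argmax and avoids depleted rows", {
  set.seed(2)
  w <- sample_dense_world(5, 2)
  m <- posterior_model(5, 2)
  # deplete row (1, 1) with many observations: its PIG falls below the rest
  for (i in 1:60) m <- record_observation(m, 1, 1, step_cmc(w, 1, 1))
  tab <- utility_table(m, "pig")
  for (i in 1:10) {
    pick <- choose_unembodied(m)
    expect_equal(tab[pick$action, pick$state], max(tab))
    expect_false(pick$action == 1 && pick$state == 1)
  }
})

test_that("choose_greedy takes the column argmax with uniform tie-breaking", {
  set.seed(3)
  for (i in 1:20) {
    u <- matrix(rnorm(12), 3, 4)
    s <- sample.int(4, 1)
    expect_equal(u[choose_greedy(u, s), s], max(u[, s]))
  }
  flat <- matrix(1, 4, 2)
  picks <- replicate(4000, choose_greedy(flat, 1))
  freq <- tabulate(picks, 4) / 4000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))
  expect_error(choose_greedy(flat, 3), "out of range")
})

test_that("value iteration reduces to the utility at horizon 0 and is null on zero utility", {
  set.seed(4)
  w <- sample_dense_world(4, 2)
  u <- matrix(runif(8), 2, 4)
  expect_equal(unclass(value_iterate(u, w, horizon = 0)), u,
               ignore_attr = TRUE)
  z <- value_iterate(matrix(0, 2, 4), w, horizon = 10)
  expect_true(all(z == 0))
  bad <- w$theta; bad[1, 1, 1] <- bad[1, 1, 1] + 0.1
  expect_error(value_iterate(u, bad), "sum to 1")
})

test_that("value iteration matches brute-force action-tree enumeration", {
  set.seed(5)
  n <- 3; m <- 2; gamma <- 0.95; horizon <- 3
  th <- array(0, c(m, n, n))
  for (a in 1:m) for (s in 1:n) {
    g <- rgamma(n, 1)
    th[a, s, ] <- g / sum(g)
  }
  w <- cmc_kernel(th)
  u <- matrix(runif(m * n), m, n)
  bf_q <- function(a, s, h) {
    if (h == 0) return(u[a, s])
    u[a, s] + gamma * sum(th[a, s, ] * vapply(1:n, function(sp)
      max(vapply(1:m, function(ap) bf_q(ap, sp, h - 1), numeric(1))),
      numeric(1)))
  }
  q <- value_iterate(u, w, gamma = gamma, horizon = horizon)
  for (a in 1:m) for (s in 1:n)
    expect_equal(q[a, s], bf_q(a, s, horizon), tolerance = 1e-10)
  # the deterministic 2-step chain case: utility 1 bit at state 2 only
  chain <- cycle_world(2)
  u2 <- matrix(c(0, 1), 1, 2)
  q2 <- value_iterate(u2, chain, gamma = 0.95, horizon = 2)
  expect_equal(q2[1, 1], 0 + 0.95 * (1 + 0.95 * 0))
  expect_equal(q2[1, 2], 1 + 0.95 * (0 + 0.95 * 1))
})

test_that("LTA picks the least-taken action; CB minimizes expected state counts", {
  counts <- matrix(c(0, 5, 5, 5), 4, 1)
  expect_equal(choose_lta(counts, 1), 1)
  flat <- matrix(2L, 4, 3)
  picks <- replicate(2000, choose_lta(flat, 2))
  expect_true(all(abs(tabulate(picks, 4) / 2000 - 0.25) < 0.04))
  # pigeonhole: simulated LTA visits every action equally often
  ac <- matrix(0L, 4, 1)
  for (i in 1:60) {
    a <- choose_lta(ac, 1)
    ac[a, 1] <- ac[a, 1] + 1L
  }
  expect_true(all(ac == 15L))

  set.seed(6)
  w <- teleport_world(4, c(2, 3))
  m <- posterior_model(4, 2)
  for (i in 1:200) {
    a <- sample.int(2, 1); s <- sample.int(4, 1)
    m <- record_observation(m, a, s, step_cmc(w, s, a))
  }
  sc <- c(10, 10, 0, 10)                 # state 3 unvisited
  expect_equal(choose_cb(m, sc, 1), 2)   # action 2 reaches state 3
  # matches the brute-force expectation on random models
  for (i in 1:10) {
    scr <- runif(4, 0, 20)
    expected <- vapply(1:2, function(a) sum(m$theta_hat[a, 1, ] * scr),
                       numeric(1))
    expect_equal(choose_cb(m, scr, 1), which.min(expected))
  }
})

test_that("the PEIG(Q) update matches hand arithmetic and validates inputs", {
  q <- matrix(0, 2, 3)
  q[2, 2] <- 0.4
  out <- peig_q_update(q, a = 1, s = 1, s_next = 2, reward = 0.3,
                       learning_rate = 0.1, gamma = 0.95)
  expect_equal(out[1, 1], 0.9 * 0 + 0.1 * (0.3 + 0.95 * 0.4))
  expect_equal(out[2, 2], 0.4)           # other entries untouched
  expect_error(peig_q_agent(learning_rate = 0), "learning_rate")
  expect_error(peig_q_agent(epsilon = 2), "epsilon")
  expect_equal(peig_q_agent()$name, "peig_q")
})

test_that("run_exploration traces are internally consistent and replayable", {
  set.seed(7)
  w <- sample_dense_world(5, 2)
  for (strat in c("random", "pig_greedy", "unembodied", "pig_vi", "lta",
                  "cb", "peig_q")) {
    tr <- run_exploration(w, strat, n_steps = 60, eval_every = 7, seed = 101)
    expect_equal(tr$model$total, 60L)
    expect_equal(sum(tr$model$counts), 60)
    expect_equal(tr$eval_times[1], 0L)
    expect_equal(tr$eval_times[length(tr$eval_times)], 60L)
    # embodied agents act from where they are; unembodied teleports
    if (strat != "unembodied")
      expect_equal(tr$origins, tr$states[-length(tr$states)])
    # replay through the R update path: identical model and I_M curve
    rp <- replay_missing_info(w, tr)
    expect_equal(rp$missing_info, tr$missing_info, tolerance = 1e-8)
    expect_equal(rp$model$theta_hat, tr$model$theta_hat, tolerance = 1e-12)
    expect_equal(rp$model$counts, tr$model$counts)
  }
  # 1-2-3 worlds replay under the discrete matched prior
  o <- sample_onetwothree_world()
  tro <- run_exploration(o, "pig_greedy", n_steps = 80, seed = 11)
  rpo <- replay_missing_info(o, tro)
  expect_equal(rpo$missing_info, tro$missing_info, tolerance = 1e-8)
  # mazes replay under the structured geometry-aware prior
  mz <- sample_maze_world()
  trm <- run_exploration(mz, "pig_vi", n_steps = 60, seed = 12)
  rpm <- replay_missing_info(mz, trm)
  expect_equal(rpm$missing_info, trm$missing_info, tolerance = 1e-8)
  expect_equal(rpm$model$theta_hat, trm$model$theta_hat, tolerance = 1e-12)
  expect_error(run_exploration(w, "warp_drive", 10), "unknown strategy")
})

test_that("greedy PIG traces always pick a PIG-maximal action", {
  set.seed(8)
  w <- sample_dense_world(4, 3)
  tr <- run_exploration(w, "pig_greedy", n_steps = 40, seed = 5)
  m <- posterior_model(4, 3)
  for (t in seq_len(tr$n_steps)) {
    s <- tr$origins[t]
    pigs <- vapply(1:3, function(a) predicted_information_gain(m, a, s),
                   numeric(1))
    expect_lte(max(pigs) - pigs[tr$actions[t]], 1e-9)
    m <- record_observation(m, tr$actions[t], s, tr$states[t + 1])
  }
})

test_that("PIG(VI) with horizon 0 reproduces PIG(greedy) action-for-action", {
  set.seed(9)
  w <- sample_dense_world(6, 3)
  tr_g <- run_exploration(w, "pig_greedy", n_steps = 100, seed = 77)
  tr_v <- run_exploration(w, list(name = "pig_vi", horizon = 0L),
                          n_steps = 100, seed = 77)
  expect_identical(tr_v$actions, tr_g$actions)
  expect_identical(tr_v$states, tr_g$states)
  expect_equal(tr_v$missing_info, tr_g$missing_info)
})

test_that("zero-step runs record only the prior missing information", {
  set.seed(10)
  w <- sample_dense_world(5, 2)
  tr <- run_exploration(w, "random", n_steps = 0, seed = 1)
  expect_equal(tr$eval_times, 0L)
  expect_equal(tr$missing_info,
               missing_information(w, posterior_model(5, 2)))
})

test_that("missing information decreases in expectation for every strategy", {
  set.seed(12)
  strategies <- c("random", "pig_greedy", "pig_vi", "lta", "cb", "peig_q",
                  "unembodied", "pmc_vi", "plc_vi", "pig_vi_plus")
  w <- sample_dense_world()
  for (strat in strategies) {
    finals <- vapply(1:8, function(i) {
      tr <- run_exploration(w, strat, n_steps = 150, seed = 1000 + i)
      tr$missing_info[length(tr$missing_info)]
    }, numeric(1))
    expect_lt(mean(finals), missing_information(w, posterior_model(10, 4)))
  }
})

test_that("trace export writes the step table and curve summary", {
  set.seed(13)
  w <- sample_dense_world(4, 2)
  tr <- run_exploration(w, "random", n_steps = 25, seed = 3)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_trace(tr, csv, js)
  steps <- read.csv(csv)
  expect_equal(nrow(steps), 25)
  expect_equal(steps$state, tr$states[-1])
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$missing_info, tr$missing_info, tolerance = 1e-12)
  unlink(c(csv, js))
})
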