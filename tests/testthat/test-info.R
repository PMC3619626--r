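test_that("KL divergence matches closed forms and flags infinite support loss", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log2(1.5) + 0.25 * log2(0.5), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)), 0.18872,
               tolerance = 1e-5)
  expect_identical(kl_divergence(c(0.5, 0.5), c(1, 0)), Inf)
  expect_equal(kl_divergence(c(0, 1), c(0, 1)), 0)   # 0 log 0 convention
  set.seed(1)
  for (i in 1:20) {
    p <- rgamma(6, 1); p <- p / sum(p)
    q <- rgamma(6, 1); q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("missing information sums row divergences", {
  th <- array(0, c(2, 2, 2))
  th[, , 1] <- 1                                  # every row is (1, 0)
  w <- cmc_kernel(th)
  expect_equal(missing_information(w, w$theta), 0)
  flat <- array(0.5, c(2, 2, 2))
  expect_equal(missing_information(w, flat), 4)   # 4 rows x 1 bit
  expect_error(missing_information(w, array(0.5, c(1, 2, 2))), "mismatch")
})

test_that("information gain matches its defining identity", {
  expect_equal(information_gain(c(1, 0), c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(information_gain(c(1, 0), c(0.5, 0.5), c(2 / 3, 1 / 3)),
               log2(4 / 3), tolerance = 1e-12)
  # I_G = row KL(old) - row KL(new)
  set.seed(3)
  for (i in 1:20) {
    p <- rgamma(5, 1); p <- p / sum(p)
    old <- rgamma(5, 1); old <- old / sum(old)
    new <- rgamma(5, 1); new <- new / sum(new)
    expect_equal(information_gain(p, old, new),
                 kl_divergence(p, old) - kl_divergence(p, new),
                 tolerance = 1e-10)
  }
})

test_that("PIG, PMC and PLC match closed forms on the untouched binary row", {
  m <- posterior_model(2, 1)
  expect_equal(predicted_information_gain(m, 1, 1),
               kl_divergence(c(2 / 3, 1 / 3), c(0.5, 0.5)), tolerance = 1e-12)
  expect_equal(predicted_information_gain(m, 1, 1), 0.08170, tolerance = 1e-4)
  expect_equal(predicted_mode_change(m, 1, 1), 1 / 6, tolerance = 1e-12)
  expect_equal(predicted_L1_change(m, 1, 1), 1 / 6, tolerance = 1e-12)
})

test_that("fully identified rows have zero predicted change", {
  m <- posterior_model(10, 3, "onetwothree")
  m <- record_observation(m, 1, 5, 2)        # deterministic action learned
  expect_equal(predicted_information_gain(m, 1, 5), 0)
  expect_equal(predicted_mode_change(m, 1, 5), 0)
  expect_equal(predicted_L1_change(m, 1, 5), 0)
})

test_that("predicted changes agree with explicit outcome enumeration", {
  set.seed(8)
  for (rep in 1:4) {
    w <- sample_dense_world(6, 2)
    m <- random_model(w, 30)
    for (a in 1:2) for (s in sample.int(6, 3)) {
      cur <- m$theta_hat[a, s, ]
      hyps <- vapply(1:6, function(st) hypothetical_row(m, a, s, st),
                     numeric(6))
      expect_equal(predicted_information_gain(m, a, s),
                   sum(cur * vapply(1:6, function(st)
                     kl_divergence(hyps[, st], cur), numeric(1))),
                   tolerance = 1e-12)
      expect_equal(predicted_mode_change(m, a, s),
                   sum(cur * (apply(hyps, 2, max) - max(cur))),
                   tolerance = 1e-12)
      expect_equal(predicted_L1_change(m, a, s),
                   sum(cur * colMeans(abs(hyps - cur))),
                   tolerance = 1e-12)
    }
  }
})

test_that("PIG decreases in expectation with successive observations", {
  set.seed(15)
  n_rows <- 300
  pig_at <- matrix(0, n_rows, 3)      # after 0, 5 and 15 observations
  for (r in seq_len(n_rows)) {
    p <- rgamma(4, 1); p <- p / sum(p)
    m <- posterior_model(4, 1)
    for (k in 0:15) {
      if (k == 0) pig_at[r, 1] <- predicted_information_gain(m, 1, 1)
      if (k == 5) pig_at[r, 2] <- predicted_information_gain(m, 1, 1)
      if (k == 15) pig_at[r, 3] <- predicted_information_gain(m, 1, 1)
      m <- record_observation(m, 1, 1, sample.int(4, 1, prob = p))
    }
  }
  means <- colMeans(pig_at)
  expect_gt(means[1], means[2])
  expect_gt(means[2], means[3])
})

test_that("PEIG is the KL of the new row from the old row", {
  expect_equal(posterior_expected_information_gain(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(posterior_expected_information_gain(c(0.5, 0.5), c(2 / 3, 1 / 3)),
               0.08170, tolerance = 1e-4)
  set.seed(2)
  for (i in 1:10) {
    old <- rgamma(4, 1); old <- old / sum(old)
    new <- rgamma(4, 1); new <- new / sum(new)
    expect_gte(posterior_expected_information_gain(old, new), 0)
  }
})

test_that("utility tables are finite, labeled, and exportable", {
  set.seed(21)
  w <- sample_dense_world(5, 2)
  m <- random_model(w, 40)
  for (u in c("pig", "pmc", "plc")) {
    tab <- utility_table(m, u)
    expect_equal(dim(tab), c(2, 5))
    expect_true(all(is.finite(tab)))
    expect_identical(attr(tab, "utility_name"), u)
  }
  expect_true(all(utility_table(m, "pig") >= 0))
  path <- tempfile(fileext = ".csv")
  df <- write_utility_csv(utility_table(m, "pig"), path)
  back <- read.csv(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$value, df$value)
  unlink(path)
})

test_that("closed-form row PIG helpers agree with the model-based PIG", {
  # the audit uses O(N) closed forms; pin them to the reference implementation
  set.seed(31)
  for (rep in 1:5) {
    cnt <- rpois(8, 1.2)
    m <- posterior_model(8, 1)
    for (i in which(cnt > 0)) for (k in seq_len(cnt[i]))
      m <- record_observation(m, 1, 1, i)
    expect_equal(pigexplore:::row_pig_dirichlet(cnt, 1),
                 predicted_information_gain(m, 1, 1), tolerance = 1e-12)
  }
  for (a in 1:3) for (k in 0:(a - 1)) {
    m <- posterior_model(10, 3, "onetwothree")
    targets <- sample.int(10, k)
    for (st in targets) m <- record_observation(m, a, 2, st)
    expect_equal(pigexplore:::row_pig_123(a, k, 10),
                 predicted_information_gain(m, a, 2), tolerance = 1e-12)
  }
})
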