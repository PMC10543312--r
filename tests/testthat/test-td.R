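# TD reference learners: exact agreement with a hand-iterated tabular
# oracle, the backward-moving bump of TD(0), its absence for large lambda,
# and conservation/discounting of the per-trial integrated RPE.

# independent oracle: plain tabular TD(lambda) over a one-hot chain,
# written as an explicit double loop with no shared code
td_oracle <- function(n_trials, n_bins, cs_bin, us_bin, n_states,
                      gamma, lambda, alpha, reward = 1) {
  w <- rep(0, n_states)
  rpe <- matrix(0, n_trials, n_bins)
  for (tr in seq_len(n_trials)) {
    e <- rep(0, n_states)
    for (t in seq_len(n_bins)) {
      k_prev <- t - 1 - cs_bin + 1
      k_curr <- t - cs_bin + 1
      v_prev <- if (k_prev >= 1 && k_prev <= n_states) w[k_prev] else 0
      v_curr <- if (k_curr >= 1 && k_curr <= n_states) w[k_curr] else 0
      r <- if (t == us_bin) reward else 0
      delta <- r + gamma * v_curr - v_prev
      e <- gamma * lambda * e
      if (k_prev >= 1 && k_prev <= n_states)
        e[k_prev] <- e[k_prev] + 1
      w <- w + alpha * delta * e
      rpe[tr, t] <- delta
    }
  }
  rpe
}

test_that("TD(0) over a 5-state chain matches the hand-iterated oracle exactly", {
  m <- td_model(5, gamma = 1, lambda = 0, alpha = 0.2)
  out <- run_td_session(m, n_trials = 12, cs_bin = 2, us_bin = 6,
                        n_bins = 8)
  ref <- td_oracle(12, 8, 2, 6, 5, gamma = 1, lambda = 0, alpha = 0.2)
  expect_equal(out$rpe, ref, tolerance = 1e-12)
})

test_that("TD(lambda) matches the oracle for discounted, trace-bearing settings", {
  m <- td_model(10, gamma = 0.95, lambda = 0.7, alpha = 0.1)
  out <- run_td_session(m, n_trials = 20, cs_bin = 3, us_bin = 12,
                        n_bins = 16)
  ref <- td_oracle(20, 16, 3, 12, 10, gamma = 0.95, lambda = 0.7,
                   alpha = 0.1)
  expect_equal(out$rpe, ref, tolerance = 1e-12)
})

test_that("naive model: zero RPE without reward, unit RPE at an unexpected reward", {
  m <- td_model(10, lambda = 0)
  out <- run_td_session(m, n_trials = 1, cs_bin = 2, us_bin = 9,
                        n_bins = 12, reward = 0)
  expect_true(all(out$rpe == 0))
  out <- run_td_session(td_model(10, lambda = 0), n_trials = 1,
                        cs_bin = 2, us_bin = 9, n_bins = 12)
  expect_equal(out$rpe[1, 9], 1)
  expect_equal(sum(out$rpe[1, -9] != 0), 0)
  # n_trials = 0 gives an empty matrix
  out0 <- run_td_session(td_model(5), n_trials = 0, cs_bin = 2,
                         us_bin = 4, n_bins = 6)
  expect_equal(dim(out0$rpe), c(0, 6))
})

test_that("TD(0) RPE peak migrates backward one state per trial", {
  m <- td_model(25, gamma = 1, lambda = 0, alpha = 1)
  out <- run_td_session(m, n_trials = 20, cs_bin = 3, us_bin = 23,
                        n_bins = 28)
  peaks <- apply(out$rpe, 1, which.max)
  expect_equal(peaks[1], 23)
  # with alpha = 1 the bump moves exactly one bin per trial until the cue
  expect_equal(peaks[1:19], seq(23, by = -1, length.out = 19))
})

test_that("converged undiscounted model transfers the RPE to the cue", {
  m <- td_model(25, gamma = 1, lambda = 0.9, alpha = 0.1)
  out <- run_td_session(m, n_trials = 500, cs_bin = 3, us_bin = 23,
                        n_bins = 28)
  last <- out$rpe[500, ]
  expect_lt(abs(last[23]), 0.02)      # reward-time RPE ~ 0
  expect_equal(last[3], 1, tolerance = 0.05)  # cue-time RPE ~ reward
  # converged value function equals the reward on all pre-reward states
  expect_equal(unname(out$model$w[1:20]), rep(1, 20), tolerance = 0.05)
})

test_that("large lambda removes the interior moving bump", {
  m <- td_model(25, gamma = 1, lambda = 0.9, alpha = 0.1)
  out <- run_td_session(m, n_trials = 60, cs_bin = 3, us_bin = 23,
                        n_bins = 28)
  interior <- out$rpe[, 5:21]
  expect_lt(max(interior), 0.1 * out$rpe[1, 23])
})

test_that("TD(lambda = 0) reproduces TD(0) weight trajectories exactly", {
  a <- run_td_session(td_model(8, lambda = 0, alpha = 0.3), 15,
                      cs_bin = 2, us_bin = 8, n_bins = 10)
  b <- run_td_session(td_model(8, lambda = 0, alpha = 0.3), 15,
                      cs_bin = 2, us_bin = 8, n_bins = 10)
  expect_identical(a$rpe, b$rpe)
  expect_identical(a$model$w, b$model$w)
})

test_that("integrated RPE is conserved at gamma = 1 and decays for gamma < 1", {
  tot1 <- integrated_rpe(run_td_session(td_model(25, gamma = 1,
    lambda = 0.9, alpha = 0.1), 80, cs_bin = 3, us_bin = 23,
    n_bins = 28)$rpe)
  expect_lt(max(abs(tot1 - tot1[1])) / tot1[1], 0.01)
  tot95 <- integrated_rpe(run_td_session(td_model(25, gamma = 0.95,
    lambda = 0.9, alpha = 0.1), 80, cs_bin = 3, us_bin = 23,
    n_bins = 28)$rpe)
  expect_true(all(diff(tot95) <= 1e-9))
  # totals never exceed the first unexpected-reward total, for every gamma
  for (g in c(1, 0.99, 0.95, 0.8)) {
    tot <- integrated_rpe(run_td_session(td_model(25, gamma = g,
      lambda = 0.9, alpha = 0.1), 60, cs_bin = 3, us_bin = 23,
      n_bins = 28)$rpe)
    expect_true(all(tot <= tot[1] + 1e-9))
  }
  expect_equal(integrated_rpe(matrix(0, 3, 4)), rep(0, 3))
})
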