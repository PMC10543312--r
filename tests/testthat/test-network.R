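# Network assembly and single-trial behavior.  Small populations keep these
# fast; the full-size study conditions are exercised in the acceptance
# tests.

small_net <- function(stimuli = "cs1", seed = 1, n = 40, n_vta = 40, ...)
  flex_network(stimuli, n = n, n_vta = n_vta, seed = seed, ...)

test_that("construction is deterministic given the seed", {
  a <- flex_network("cs1", n = 20, n_vta = 20, seed = 42)
  b <- flex_network("cs1", n = 20, n_vta = 20, seed = 42)
  for (nm in names(a$projections))
    expect_identical(a$projections[[nm]]$W, b$projections[[nm]]$W)
  expect_identical(a$groups$timer_cs1$tonic_extra,
                   b$groups$timer_cs1$tonic_extra)
})

test_that("declared architecture has one column per stimulus and shared VTA", {
  net <- flex_network(c("a", "b"), n = 10, n_vta = 12, seed = 1)
  expect_setequal(names(net$groups),
                  c("cs_a", "timer_a", "inh_a", "msg_a",
                    "cs_b", "timer_b", "inh_b", "msg_b",
                    "us", "da", "gaba"))
  expect_equal(net$groups$da$n, 12)
  # the three plastic pathways exist per column, everything else is fixed
  plastic <- names(which(vapply(net$projections, function(p) p$rule != 0L,
                                logical(1))))
  expect_setequal(plastic, c("tt_a", "cd_a", "mg_a", "tt_b", "cd_b",
                             "mg_b"))
  expect_error(network_spec(character(0)), "at least one")
  expect_error(network_spec(c("x", "x")), "unique")
  expect_error(network_spec("us"), "reserved")
})

test_that("sparse projections realize the declared connection density", {
  net <- flex_network("cs1", n = 100, n_vta = 100, seed = 3)
  W <- net$projections$ud$W
  k <- sum(W > 0)
  # binomial 99% CI around p * n_pre * n_post
  p <- flex_defaults()$conn$ud$p
  n <- length(W)
  expect_gt(k, qbinom(0.005, n, p))
  expect_lt(k, qbinom(0.995, n, p))
  expect_true(all(W >= 0))
})

test_that("a trial without learning leaves all weights bit-identical", {
  net <- small_net()
  set.seed(5)
  out <- run_trial(net, data.frame(stimulus = c("cs1", "us"),
                                   onset = c(100, 700),
                                   duration = c(150, 50), magnitude = 1),
                   trial_length = 900, learning = FALSE)
  for (nm in names(net$projections))
    expect_identical(out$net$projections[[nm]]$W, net$projections[[nm]]$W)
})

test_that("two sessions with the same seeds give identical trajectories", {
  net <- small_net()
  sess <- trace_conditioning(n_trials = 2, us_onset = 600,
                             trial_length = 900)
  h1 <- run_session(net, sess, seed = 11)
  h2 <- run_session(net, sess, seed = 11)
  expect_identical(h1$weights, h2$weights)
  expect_identical(h1$trials[[2]]$pop_rates, h2$trials[[2]]$pop_rates)
})

test_that("a reward pulse drives dopamine above the neutral band", {
  # full-size reward module: the neutral band is calibrated against the
  # population-mean rate fluctuations of 100 neurons
  net <- flex_network("cs1", n = 40, n_vta = 100, seed = 1)
  set.seed(21)
  out <- run_trial(net, data.frame(stimulus = "us", onset = 300,
                                   duration = 50, magnitude = 1),
                   trial_length = 700, learning = FALSE)
  rec <- out$recording
  t <- rec$time
  expect_gt(max(rec$D[t > 300 & t < 550]), 0)
  # and reinforcement is (almost always) zero away from the reward
  expect_lt(mean(rec$D[t < 250] != 0), 0.1)
})

test_that("timer_duration returns the width of a rectangular rate profile", {
  rec <- structure(list(
    time = seq(1, 1000),
    pop_rates = cbind(timer_x = c(rep(40, 400), rep(0, 600))),
    events = data.frame(stimulus = "x", onset = 0, duration = 100,
                        magnitude = 1),
    record_every = 1, r0 = 5, theta = 1), class = "flex_trial")
  expect_equal(timer_duration(rec, "x", cs_onset = 0), 400, tolerance = 1)
  # silent timer is reported as absent, not zero
  rec$pop_rates[, 1] <- 0
  expect_true(is.na(timer_duration(rec, "x", cs_onset = 0)))
})

test_that("unknown stimuli and invalid events are rejected", {
  net <- small_net()
  expect_error(run_trial(net, data.frame(stimulus = "zz", onset = 0,
                                         duration = 10, magnitude = 1)),
               "unknown stimulus")
  expect_error(run_trial(net, data.frame(stimulus = "cs1", onset = 1590,
                                         duration = 50, magnitude = 1),
                         trial_length = 1600), "trial_length")
})

test_that("step_network advances state without resetting it", {
  net <- small_net()
  set.seed(8)
  out1 <- step_network(net, drive = c(cs1 = 1), n_steps = 200,
                       learning = FALSE)
  s1 <- out1$net$state$cs_cs1$r
  expect_gt(mean(s1), 1)  # cue relay active
  out2 <- step_network(out1$net, n_steps = 10, learning = FALSE)
  # rates persist across calls (no reset)
  expect_gt(mean(out2$net$state$cs_cs1$r), 0.5 * mean(s1))
})

test_that("coef and print surface the plastic pathway weights", {
  net <- small_net()
  w <- coef(net)
  expect_named(w, c("tt_cs1", "cd_cs1", "mg_cs1"))
  expect_output(print(net), "plastic pathways")
})
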