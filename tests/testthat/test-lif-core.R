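# Membrane, synaptic-activation and rate-filter dynamics against closed
# forms and mean-field limits.

quiet_params <- function(...) neuron_params(sigma = 0, ...)

run_free <- function(v0, n_steps, dt, gE = 0, gI = 0,
                     params = quiet_params()) {
  g <- neuron_group(length(v0), params)
  g$v <- as.double(v0)
  out <- matrix(NA_real_, n_steps, length(v0))
  for (i in seq_len(n_steps)) {
    g <- step_membrane(g, rep(gE, g$n), rep(gI, g$n), dt)
    out[i, ] <- g$v
  }
  out
}

test_that("membrane at leak equilibrium stays there with no input", {
  tr <- run_free(v0 = rep(-70, 4), n_steps = 200, dt = 0.5)
  expect_true(all(tr == -70))
})

test_that("free membrane decay matches the closed-form exponential", {
  p <- quiet_params()
  v0 <- -55
  dt <- 0.01
  n <- 2000
  tr <- run_free(v0, n, dt)
  t <- seq_len(n) * dt
  exact <- p$EL + (v0 - p$EL) * exp(-p$gL * t / p$C)
  expect_lt(max(abs(tr[, 1] - exact)), 0.05)
  # order-1 convergence: halving dt roughly halves the maximum error
  err_at <- function(dt) {
    n <- round(20 / dt)
    tr <- run_free(v0, n, dt)
    t <- seq_len(n) * dt
    max(abs(tr[, 1] - (p$EL + (v0 - p$EL) * exp(-p$gL * t / p$C))))
  }
  e1 <- err_at(0.4); e2 <- err_at(0.2)
  expect_gt(e1 / e2, 1.6)
  expect_lt(e1 / e2, 2.4)
})

test_that("constant subthreshold conductance drives v to the predicted steady state", {
  p <- quiet_params()
  gE <- 2  # steady state (gL*EL + gE*EE)/(gL + gE) = -58.33 mV, subthreshold
  v_inf <- (p$gL * p$EL + gE * p$EE) / (p$gL + gE)
  tr <- run_free(p$EL, n_steps = 4000, dt = 0.1, gE = gE)
  expect_equal(tr[nrow(tr), 1], v_inf, tolerance = 1e-3)
  expect_lt(max(tr), v_inf + 1e-6)  # no overshoot, no spike
})

test_that("threshold crossing spikes, resets and enforces refractoriness", {
  p <- quiet_params()
  g <- neuron_group(1, p)
  gE <- 20  # suprathreshold drive
  spikes <- integer(0)
  vs <- numeric(0)
  for (i in 1:400) {
    g <- step_membrane(g, gE, 0, dt = 0.5)
    spikes <- c(spikes, g$spikes)
    vs <- c(vs, g$v)
  }
  expect_gt(sum(spikes), 0)
  # reset after each spike
  expect_true(all(vs[spikes == 1] == p$vreset))
  # refractory: no two spikes closer than tref
  isi <- diff(which(spikes == 1)) * 0.5
  expect_true(all(isi >= p$tref))
  expect_true(all(vs <= p$vth))
})

test_that("non-finite state is a hard failure naming the neuron", {
  g <- neuron_group(3)
  g$v[2] <- NaN
  expect_error(step_membrane(g, rep(0, 3), rep(0, 3), dt = 0.1),
               "neuron 2")
  expect_error(step_membrane(neuron_group(2), 0, 0, dt = -1), "dt")
  expect_error(step_membrane(neuron_group(2), -1, 0, dt = 0.1),
               "conductances")
})

test_that("synaptic activation jumps by rho*(1-s) and stays in [0, 1]", {
  p <- neuron_params(rho = 0.4)
  g <- neuron_group(1, p)
  # one spike from s = 0 -> s = rho, then exponential decay
  g <- step_synaptic_activation(g, spikes = 1L, dt = 1e-9)
  expect_equal(g$s_fast, 0.4, tolerance = 1e-6)
  s0 <- g$s_fast
  for (i in 1:50) g <- step_synaptic_activation(g, spikes = 0L, dt = 0.1)
  expect_equal(g$s_fast, s0 * exp(-5 / p$tau_s_fast), tolerance = 0.02)
  # saturation: from s = 1 a spike changes nothing
  g$s_fast <- 1
  g <- step_synaptic_activation(g, spikes = 1L, dt = 1e-9)
  expect_equal(g$s_fast, 1)
  # random spike trains never leave [0, 1]
  set.seed(42)
  g <- neuron_group(5, p)
  for (i in 1:500) {
    g <- step_synaptic_activation(g, spikes = rbinom(5, 1, 0.3), dt = 0.5)
    expect_true(all(g$s_fast >= 0 & g$s_fast <= 1))
    expect_true(all(g$s_slow >= 0 & g$s_slow <= 1))
  }
})

test_that("mean activation under Poisson spiking matches the mean-field fixed point", {
  # ds/dt = -s/tau + rho (1 - s) f  =>  s* = rho f tau / (1 + rho f tau)
  set.seed(7)
  p <- neuron_params(rho = 0.5, tau_s_fast = 20)
  f <- 0.04  # spikes per ms (40 Hz)
  g <- neuron_group(200, p)
  dt <- 0.5
  keep <- numeric(0)
  for (i in 1:4000) {
    g <- step_synaptic_activation(g, spikes = rbinom(200, 1, f * dt), dt)
    if (i > 800) keep <- c(keep, mean(g$s_fast))
  }
  s_star <- p$rho * f * p$tau_s_fast / (1 + p$rho * f * p$tau_s_fast)
  expect_equal(mean(keep), s_star, tolerance = 0.05)
})

test_that("conductances are linear in weights and activations", {
  W <- matrix(c(1, 2, 0, 0.5), 2, 2)
  s <- c(0.2, 0.6)
  g <- compute_conductances(W, NULL, s, NULL)
  expect_equal(g$gE, as.double(W %*% s))
  g2 <- compute_conductances(2 * W, NULL, s, NULL)
  expect_equal(g2$gE, 2 * g$gE)
  expect_equal(compute_conductances(W, NULL, c(0, 0), NULL)$gE, c(0, 0))
  # single synapse: g = w * s
  expect_equal(compute_conductances(matrix(3), NULL, 0.25, NULL)$gE, 0.75)
  expect_error(compute_conductances(W, NULL, c(1, 2, 3), NULL),
               "shape mismatch")
  expect_error(compute_conductances(-W, NULL, s, NULL), ">= 0")
})

test_that("rate filter has unit area and recovers a Poisson rate", {
  p <- neuron_params(tau_r = 50)
  g <- neuron_group(1, p)
  # single spike: peak 1/tau_r (in per-ms units) = 1000/tau_r Hz
  g <- step_rate_estimate(g, spikes = 1L, dt = 1e-9)
  expect_equal(g$r, 1000 / p$tau_r, tolerance = 1e-6)
  r0 <- g$r
  for (i in 1:100) g <- step_rate_estimate(g, spikes = 0L, dt = 0.5)
  expect_equal(g$r, r0 * exp(-50 / p$tau_r), tolerance = 0.05)
  # stationary 20 Hz Poisson train averages to 20 Hz
  set.seed(11)
  g <- neuron_group(100, p)
  keep <- numeric(0)
  for (i in 1:6000) {
    g <- step_rate_estimate(g, spikes = rbinom(100, 1, 0.02 * 0.5),
                            dt = 0.5)
    if (i > 1000) keep <- c(keep, mean(g$r))
  }
  expect_equal(mean(keep), 20, tolerance = 0.06 * 20)
})

test_that("parameter invariants are enforced", {
  expect_error(neuron_params(EI = -60), "EI <= EL")
  expect_error(neuron_params(rho = 0), "rho")
  expect_error(neuron_params(tau_r = -1), "positive")
})
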