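# Two-trace learning rule: reinforcement map, Hebbian gating, trace
# dynamics against an independent high-resolution ODE oracle, the weight
# updates and the fixed-point residual.

test_that("dopamine reinforcement is the three-branch piecewise-linear map", {
  expect_equal(dopamine_reinforcement(5, 5, 1), 0)
  expect_equal(dopamine_reinforcement(6, 5, 1), 0)   # band edge
  expect_equal(dopamine_reinforcement(8, 5, 1), 2)   # r0 + theta + 2
  expect_equal(dopamine_reinforcement(4, 5, 1), 0)   # lower edge
  expect_equal(dopamine_reinforcement(1, 5, 1), -3)  # r0 - theta - 3
  # continuity and zero inside the band, on a dense grid
  r <- seq(0, 12, by = 0.01)
  D <- dopamine_reinforcement(r, 5, 1)
  expect_true(all(D[r > 4 & r < 6] == 0))
  expect_lt(max(abs(diff(D))), 0.011)  # piecewise linear, slope <= 1
  expect_error(dopamine_reinforcement(5, 5, -1), "theta")
})

test_that("Hebbian activity is the rate product, divisively gated in PFC", {
  expect_equal(hebbian_activity(10, 5, region = "vta"), 50)
  expect_equal(hebbian_activity(10, 5, D = 100, region = "vta"), 50)
  # alpha*D = 9 -> 10-fold suppression
  expect_equal(hebbian_activity(10, 5, D = 9, region = "pfc", alpha = 1), 5)
  # gating only for positive reinforcement
  expect_equal(hebbian_activity(10, 5, D = -9, region = "pfc", alpha = 1),
               50)
  expect_equal(hebbian_activity(0, 5, region = "pfc"), 0)
  # vector input gives the outer product (post x pre)
  H <- hebbian_activity(c(1, 2), c(3, 4, 5), region = "vta")
  expect_equal(dim(H), c(3, 2))
  expect_equal(H[2, 2], 8)
  expect_error(hebbian_activity(-1, 5), ">= 0")
})

test_that("traces decay exponentially without Hebbian drive", {
  tp <- trace_params()
  tr <- trace_pair(1, 1, tp)
  tr$Tp[] <- 0.8; tr$Td[] <- 0.5
  for (i in 1:200) tr <- step_traces(tr, 0, dt = 1)
  expect_equal(tr$Tp[1, 1], 0.8 * exp(-200 / tp$tau_p), tolerance = 0.01)
  expect_equal(tr$Td[1, 1], 0.5 * exp(-200 / tp$tau_d), tolerance = 0.01)
})

test_that("constant drive reaches the analytic trace fixed point and saturates", {
  # tau dT/dt = -T + eta H (Tmax - T)  =>  T* = eta H Tmax / (1 + eta H)
  tp <- trace_params(eta_p = 0.01, tau_p = 100, tmax_p = 2,
                     eta_d = 0.02, tau_d = 50, tmax_d = 1.5)
  tr <- trace_pair(1, 1, tp)
  H <- 300
  for (i in 1:8000) tr <- step_traces(tr, H, dt = 0.25)
  expect_equal(tr$Tp[1, 1], 0.01 * H * 2 / (1 + 0.01 * H),
               tolerance = 1e-3)
  expect_equal(tr$Td[1, 1], 0.02 * H * 1.5 / (1 + 0.02 * H),
               tolerance = 1e-3)
  # at saturation the derivative is non-positive
  tr$Tp[] <- tp$tmax_p
  before <- tr$Tp[1, 1]
  tr <- step_traces(tr, 1e4, dt = 0.5)
  expect_lte(tr$Tp[1, 1], before)
})

test_that("trace integration matches an independent ODE solver on random drive", {
  skip_if_not_installed("deSolve")
  set.seed(3)
  tp <- trace_params()
  # piecewise-constant random Hebbian profile, 2 s
  knots <- seq(0, 2000, by = 100)
  hvals <- runif(length(knots), 0, 2000)
  Hfun <- function(t) hvals[pmin(length(hvals), findInterval(t, knots) + 0)]
  rhs <- function(t, y, parms) {
    H <- Hfun(t)
    list(c((-y[1] + tp$eta_p * H * (tp$tmax_p - y[1])) / tp$tau_p,
           (-y[2] + tp$eta_d * H * (tp$tmax_d - y[2])) / tp$tau_d))
  }
  sol <- deSolve::ode(c(0, 0), seq(0, 2000, by = 10), rhs, NULL,
                      method = "ode45")
  tr <- trace_pair(1, 1, tp)
  dt <- 0.25
  path <- matrix(NA_real_, 0, 2)
  for (i in seq_len(2000 / dt)) {
    tr <- step_traces(tr, Hfun((i - 1) * dt), dt)
    if ((i * dt) %% 10 == 0) path <- rbind(path, c(tr$Tp[1], tr$Td[1]))
  }
  ref <- sol[-1, 2:3]
  expect_lt(max(abs(path - ref)) / max(ref), 0.01)
})

test_that("weight update follows the sign table of the competitive rule", {
  tr <- trace_pair(2, 2)
  tr$Tp[] <- 0.6; tr$Td[] <- 0.2
  W <- matrix(0.5, 2, 2)
  expect_equal(apply_weight_update(W, tr, D = 0, eta = 1, dt = 1), W)
  Wp <- apply_weight_update(W, tr, D = 2, eta = 0.1, dt = 1)
  expect_true(all(Wp > W))                     # D>0, Tp>Td -> potentiate
  Wm <- apply_weight_update(W, tr, D = -2, eta = 0.1, dt = 1)
  expect_true(all(Wm < W))                     # D<0, Tp>Td -> depress
  tr$Td[] <- 0.6                               # traces equal -> fixed point
  expect_equal(apply_weight_update(W, tr, D = 5, eta = 1, dt = 1), W)
  # clipping to [0, wmax]
  tr$Td[] <- 0.2
  expect_true(all(apply_weight_update(W, tr, D = 1e4, eta = 1, dt = 1,
                                      wmax = 1) <= 1))
  expect_true(all(apply_weight_update(W, tr, D = -1e4, eta = 1,
                                      dt = 1) >= 0))
})

test_that("dopamine-modulated Hebbian update has the right sign structure", {
  W <- matrix(0.3, 2, 2)
  expect_equal(dopamine_hebbian_update(W, c(1, 1), c(1, 1), D = 0,
                                       eta = 1, dt = 1), W)
  expect_equal(dopamine_hebbian_update(W, c(0, 0), c(5, 5), D = 3,
                                       eta = 1, dt = 1), W)
  Wd <- dopamine_hebbian_update(W, c(2, 2), c(3, 3), D = -1, eta = 0.01,
                                dt = 1)
  expect_true(all(Wd < W))
  expect_true(all(Wd >= 0))
})

test_that("fixed-point residual reduces to the trace difference at the reward impulse", {
  t <- seq(0, 100, by = 1)
  tp <- 0.5 + 0 * t; td <- 0.3 + 0 * t
  D0 <- rep(0, length(t))
  expect_equal(fixed_point_residual(D0, tp, td, dt = 1), 0)
  # unit impulse at t = 60 (width dt): residual = Tp(60) - Td(60)
  D1 <- D0; D1[61] <- 1
  tp2 <- pmax(0, 1 - t / 100); td2 <- pmax(0, 0.8 - t / 200)
  expect_equal(fixed_point_residual(D1, tp2, td2, dt = 1),
               tp2[61] - td2[61])
  # two-bump reinforcement: residual equals the sum of the two bump
  # integrals, by direct quadrature
  D2 <- D0; D2[11:15] <- 2; D2[61:65] <- 1
  manual <- sum(D2 * (tp2 - td2)) * 1
  expect_equal(fixed_point_residual(D2, tp2, td2, dt = 1), manual)
  expect_error(fixed_point_residual(D2[-1], tp2, td2, dt = 1),
               "misaligned")
})
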