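# Dopaminergic two-trace learning (dTTL): thresholded reinforcement D(t)
# from the dopamine population rate, competing LTP/LTD eligibility traces,
# the reinforcement-gated weight update, and the dopamine-modulated Hebbian
# rule used for the Messenger-to-GABA pathway.

#' Dopamine reinforcement from the DA population rate
#'
#' Piecewise-linear map of the dopamine population rate to a signed
#' reinforcement: zero inside the neutral band `(r0 - theta, r0 + theta)`,
#' and the linear excess beyond the band edges outside it.  The neutral band
#' gives robustness to the small rate fluctuations inherent in spiking
#' networks; departures from baseline in either direction reinforce or
#' depress eligible synapses.
#'
#' @param rda dopamine population rate(s), Hz.
#' @param r0 baseline rate (Hz).
#' @param theta neutral half-width (Hz), non-negative.
#' @return signed reinforcement, same length as `rda` (Hz-equivalent).
#' @export
#' @examples
#' dopamine_reinforcement(c(5, 6, 8, 1), r0 = 5, theta = 1)
dopamine_reinforcement <- function(rda, r0 = 5, theta = 1) {
  if (!is.numeric(theta) || length(theta) != 1 || theta < 0)
    stop("theta must be a single number >= 0")
  as.double(cpp_dopamine(as.double(rda), r0, theta))
}

#' Hebbian coactivity driving eligibility-trace formation
#'
#' In the reward module (VTA) the Hebbian term is the plain product of
#' pre- and postsynaptic rate estimates.  In the cortical module (PFC) the
#' product is divisively suppressed during large positive reinforcement,
#' `H = r_post r_pre / (1 + alpha * D)` for `D > 0`: large positive
#' prediction errors act as event boundaries and stop cortical traces from
#' binding across them.  Negative reinforcement leaves the product ungated.
#'
#' @param r_pre,r_post presynaptic and postsynaptic rate estimates (Hz),
#'   non-negative; vectors give the full outer-product matrix
#'   (postsynaptic x presynaptic).
#' @param D current reinforcement (see [dopamine_reinforcement()]).
#' @param region `"vta"` (plain product) or `"pfc"` (gated product).
#' @param alpha gating strength (1/Hz), used for `region = "pfc"`.
#' @return Hebbian activity matrix (or scalar for scalar inputs), >= 0.
#' @export
#' @examples
#' hebbian_activity(10, 5, region = "vta")            # 50
#' hebbian_activity(10, 5, D = 9, region = "pfc", alpha = 1)  # 5
hebbian_activity <- function(r_pre, r_post, D = 0,
                             region = c("vta", "pfc"), alpha = 0) {
  region <- match.arg(region)
  if (any(r_pre < 0) || any(r_post < 0)) stop("rates must be >= 0")
  H <- outer(as.double(r_post), as.double(r_pre))
  if (region == "pfc" && D > 0) H <- H / (1 + alpha * D)
  if (length(r_pre) == 1 && length(r_post) == 1) drop(H) else H
}

#' Eligibility-trace parameters
#'
#' Parameters of the competing LTP and LTD traces.  Each trace follows
#' `tau dT/dt = -T + eta * H * (Tmax - T)`: it activates in proportion to
#' Hebbian activity, saturates at `Tmax`, and decays with time constant
#' `tau`.  The defaults make the LTD trace dominant during and just after
#' Hebbian activation (larger saturation, faster decay) and the LTP trace
#' dominant at long delays (slower decay), so the traces cross once at a
#' short, fixed lag after activation ends.  That ordering makes the
#' trace-crossing fixed point of the weight update attractive: reinforcement
#' arriving later than the crossing potentiates, reinforcement arriving
#' earlier (or during activation) depresses.
#'
#' @param eta_p,eta_d activation constants (1/Hz^2) of the LTP and LTD
#'   traces.
#' @param tau_p,tau_d decay time constants (ms); `tau_p > tau_d`.
#' @param tmax_p,tmax_d saturation levels (dimensionless).
#' @return object of class `trace_params`.
#' @export
trace_params <- function(eta_p = 0.002, eta_d = 0.002,
                         tau_p = 1200, tau_d = 250,
                         tmax_p = 1, tmax_d = 1.3) {
  p <- list(eta_p = eta_p, eta_d = eta_d, tau_p = tau_p, tau_d = tau_d,
            tmax_p = tmax_p, tmax_d = tmax_d)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0)
      stop("trace parameter `", nm, "` must be a single positive number")
  structure(p, class = "trace_params")
}

#' Create a zeroed LTP/LTD trace pair
#'
#' @param n_post,n_pre dimensions of the synapse array (postsynaptic x
#'   presynaptic).
#' @param params a [trace_params()] object.
#' @return object of class `trace_pair` with matrices `Tp` and `Td`.
#' @export
trace_pair <- function(n_post, n_pre, params = trace_params()) {
  structure(list(Tp = matrix(0, n_post, n_pre),
                 Td = matrix(0, n_post, n_pre),
                 params = params),
            class = "trace_pair")
}

#' Advance the eligibility traces by one step
#'
#' @param traces a [trace_pair()].
#' @param H Hebbian activity per synapse (matrix or scalar, >= 0), see
#'   [hebbian_activity()].
#' @param dt time step (ms).
#' @return the updated trace pair; both traces stay within `[0, Tmax]`.
#' @export
step_traces <- function(traces, H, dt) {
  stopifnot(inherits(traces, "trace_pair"))
  if (any(H < 0)) stop("Hebbian activity must be >= 0")
  H <- matrix(as.double(H), nrow(traces$Tp), ncol(traces$Tp))
  p <- traces$params
  traces$Tp <- cpp_trace_step(traces$Tp, H, p$eta_p, p$tau_p, p$tmax_p, dt)
  traces$Td <- cpp_trace_step(traces$Td, H, p$eta_d, p$tau_d, p$tmax_d, dt)
  traces
}

#' Reinforcement-gated competitive weight update
#'
#' `dW/dt = eta * D * (Tp - Td)`: the signed reinforcement converts the
#' difference of the two eligibility traces into a weight change, clipped to
#' `[0, wmax]`.  No change when `D = 0` or the traces are equal.
#'
#' @param W weight matrix (>= 0).
#' @param traces a [trace_pair()] aligned with `W`.
#' @param D current reinforcement.
#' @param eta learning rate.
#' @param dt time step (ms).
#' @param wmax upper weight bound.
#' @return the updated weight matrix.
#' @export
apply_weight_update <- function(W, traces, D, eta, dt, wmax = Inf) {
  stopifnot(inherits(traces, "trace_pair"))
  W <- W + eta * D * (traces$Tp - traces$Td) * dt
  W[W < 0] <- 0
  W[W > wmax] <- wmax
  W
}

#' Dopamine-modulated Hebbian update
#'
#' `dW/dt = eta * D * r_post r_pre`, clipped to `[0, wmax]`.  Used for the
#' Messenger-to-GABA pathway, where the rule's own fixed point is reached
#' when the reinforcement it suppresses has been driven to zero.
#'
#' @param W weight matrix (postsynaptic x presynaptic).
#' @param r_pre,r_post rate estimates (Hz).
#' @inheritParams apply_weight_update
#' @return the updated weight matrix.
#' @export
dopamine_hebbian_update <- function(W, r_pre, r_post, D, eta, dt,
                                    wmax = Inf) {
  W <- W + eta * D * outer(as.double(r_post), as.double(r_pre)) * dt
  W[W < 0] <- 0
  W[W > wmax] <- wmax
  W
}

#' Trial integral of the weight-update fixed-point condition
#'
#' Integrates `D(t) * (Tp(t) - Td(t))` over one trial.  Learning for a
#' synapse has converged when this residual is (close to) zero: either the
#' reinforcement is zero whenever the traces differ, or positive and
#' negative contributions cancel over the trial.
#'
#' @param D_series reinforcement time series over one trial.
#' @param tp_series,td_series eligibility-trace time series, either vectors
#'   aligned with `D_series` or matrices with time in rows (one column per
#'   synapse).
#' @param dt sampling interval of the series (ms).
#' @return scalar residual (or one per column for matrix input).
#' @export
#' @examples
#' fixed_point_residual(c(0, 1, 0), c(1, 1, 1), c(1, 1, 1), dt = 1)  # 0
fixed_point_residual <- function(D_series, tp_series, td_series, dt = 1) {
  tp <- as.matrix(tp_series); td <- as.matrix(td_series)
  if (nrow(tp) != length(D_series) || nrow(td) != length(D_series) ||
      any(dim(tp) != dim(td)))
    stop("misaligned series: D, Tp and Td must share the time dimension")
  drop(crossprod(tp - td, as.double(D_series)) * dt)
}
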