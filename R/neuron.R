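# Conductance-based leaky integrate-and-fire populations: membrane dynamics,
# saturating synaptic activations on a fast (~AMPA) and a slow (~NMDA)
# channel, and online exponential-filter rate estimation.  All single-step
# updates call the same compiled kernels the network session loop uses.

.par_names <- c("C", "gL", "EL", "EE", "EI", "vth", "vreset", "tref",
                "tau_s_fast", "tau_s_slow", "rho", "rho_slow", "sigma",
                "tau_r", "tonic")

#' Leaky integrate-and-fire neuron parameters
#'
#' Parameters of a homogeneous conductance-based LIF population.  Units:
#' capacitance pF, conductances nS, potentials mV, times ms, currents pA.
#' The membrane time constant is `C/gL` (20 ms with the defaults).
#'
#' @param C membrane capacitance (pF).
#' @param gL leak conductance (nS).
#' @param EL,EE,EI leak, excitatory and inhibitory reversal potentials (mV).
#' @param vth spike threshold (mV).
#' @param vreset post-spike reset potential (mV); the membrane is clamped
#'   here for the refractory period.
#' @param tref absolute refractory period (ms).
#' @param tau_s_fast,tau_s_slow decay time constants (ms) of the fast and
#'   slow synaptic activation channels carried by every neuron.
#' @param rho per-spike activation increment factor of the fast channel,
#'   0 < rho <= 1; each spike moves the activation by `rho * (1 - s)`,
#'   which keeps `s` in \[0, 1\].
#' @param rho_slow per-spike increment factor of the slow channel
#'   (defaults to `rho`); values below 1 keep slow (NMDA-like) drive graded
#'   in firing rate rather than saturating at a few Hz.
#' @param sigma white current-noise amplitude (pA sqrt(ms)); the per-step
#'   voltage kick has standard deviation `sigma * sqrt(dt) / C`.
#' @param tau_r rate-estimate filter time constant (ms); the filter has unit
#'   area so a stationary Poisson train at f Hz averages to f.
#' @param tonic constant tonic input current (pA).
#' @return object of class `neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$EL
neuron_params <- function(C = 200, gL = 10, EL = -70, EE = 0, EI = -80,
                          vth = -50, vreset = EL, tref = 2,
                          tau_s_fast = 5, tau_s_slow = 100, rho = 1,
                          rho_slow = rho, sigma = 0, tau_r = 50,
                          tonic = 0) {
  p <- list(C = C, gL = gL, EL = EL, EE = EE, EI = EI, vth = vth,
            vreset = vreset, tref = tref, tau_s_fast = tau_s_fast,
            tau_s_slow = tau_s_slow, rho = rho, rho_slow = rho_slow,
            sigma = sigma, tau_r = tau_r, tonic = tonic)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]))
      stop("neuron parameter `", nm, "` must be a single finite number")
  if (!(p$EI <= p$EL && p$EL < p$vth && p$vth <= p$EE))
    stop("reversal potentials must satisfy EI <= EL < vth <= EE")
  if (p$C <= 0 || p$gL <= 0 || p$tau_s_fast <= 0 || p$tau_s_slow <= 0 ||
      p$tau_r <= 0 || p$tref < 0)
    stop("capacitance, conductance and time constants must be positive")
  if (p$rho <= 0 || p$rho > 1) stop("rho must lie in (0, 1]")
  if (p$rho_slow <= 0 || p$rho_slow > 1)
    stop("rho_slow must lie in (0, 1]")
  if (p$sigma < 0) stop("sigma must be >= 0")
  structure(p, class = "neuron_params")
}

# flatten to the fixed-layout numeric vector the C++ kernels expect
par_vector <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  unlist(params[.par_names], use.names = FALSE)
}

#' Create a homogeneous LIF population
#'
#' @param n number of neurons.
#' @param params a [neuron_params()] object.
#' @return object of class `neuron_group` holding the per-neuron state:
#'   membrane potential `v` (mV), synaptic activations `s_fast`, `s_slow`
#'   (dimensionless, in \[0, 1\]), rate estimate `r` (Hz), refractory clock
#'   `ref_until` (ms) and the spike indicators of the most recent step.
#' @export
#' @examples
#' g <- neuron_group(10)
#' all(g$v == -70)
neuron_group <- function(n, params = neuron_params()) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  n <- as.integer(n)
  structure(list(
    n = n, params = params,
    v = rep(params$EL, n),
    s_fast = rep(0, n), s_slow = rep(0, n),
    r = rep(0, n),
    ref_until = rep(-1e18, n),
    spikes = integer(n), t = 0
  ), class = "neuron_group")
}

check_group <- function(group) {
  if (!inherits(group, "neuron_group")) stop("not a `neuron_group`")
  bad <- which(!is.finite(group$v))
  if (length(bad))
    stop("non-finite membrane potential at neuron ", bad[1])
  invisible(group)
}

#' Advance membrane potentials by one forward-Euler step
#'
#' Integrates the conductance-based membrane equation
#' `C dv/dt = gL (EL - v) + gE (EE - v) + gI (EI - v) + tonic + noise`;
#' neurons crossing threshold emit a spike, reset to `vreset` and are clamped
#' there for the refractory period.
#'
#' @param group a [neuron_group()].
#' @param gE,gI excitatory and inhibitory conductances per neuron (nS),
#'   non-negative.
#' @param dt time step (ms), positive.
#' @param noise logical; include the stochastic current term (uses the R
#'   random stream).
#' @return the updated group; `group$spikes` holds the 0/1 spike indicators
#'   of this step.
#' @export
#' @examples
#' g <- neuron_group(5)
#' g <- step_membrane(g, gE = rep(0, 5), gI = rep(0, 5), dt = 0.1)
#' sum(g$spikes)
step_membrane <- function(group, gE, gI, dt, noise = FALSE) {
  check_group(group)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number")
  gE <- rep_len(as.double(gE), group$n)
  gI <- rep_len(as.double(gI), group$n)
  if (any(gE < 0) || any(gI < 0)) stop("conductances must be >= 0")
  res <- cpp_lif_step(group$v, group$ref_until, gE, gI,
                      par_vector(group$params), group$t, dt, noise)
  group$v <- as.double(res$v)
  group$ref_until <- as.double(res$ref_until)
  group$spikes <- as.integer(res$spikes)
  group$t <- group$t + dt
  group
}

#' Advance synaptic activations by one step
#'
#' Both activation channels decay exponentially (with their own time
#' constants) and jump by `rho * (1 - s)` on a spike, which confines them to
#' \[0, 1\] for any spike sequence.
#'
#' @param group a [neuron_group()].
#' @param spikes 0/1 spike indicators (defaults to the group's last step).
#' @param dt time step (ms).
#' @return the updated group.
#' @export
step_synaptic_activation <- function(group, spikes = group$spikes, dt) {
  check_group(group)
  spikes <- as.integer(rep_len(spikes, group$n))
  group$s_fast <- as.double(cpp_syn_step(group$s_fast, spikes,
                                         group$params$tau_s_fast,
                                         group$params$rho, dt))
  group$s_slow <- as.double(cpp_syn_step(group$s_slow, spikes,
                                         group$params$tau_s_slow,
                                         group$params$rho_slow, dt))
  group
}

#' Conductances from presynaptic activations
#'
#' Computes `g = W s` for the excitatory and inhibitory channels.  Weights
#' are non-negative; the sign of a connection is carried by the channel it
#' feeds, not by the weight.
#'
#' @param weights_exc,weights_inh non-negative weight matrices
#'   (postsynaptic x presynaptic, nS); `NULL` for no input on that channel.
#' @param s_pre_exc,s_pre_inh presynaptic activation vectors.
#' @return list with vectors `gE` and `gI`.
#' @export
#' @examples
#' compute_conductances(matrix(2), NULL, 0.5, NULL)$gE  # 1 nS
compute_conductances <- function(weights_exc = NULL, weights_inh = NULL,
                                 s_pre_exc = NULL, s_pre_inh = NULL) {
  one <- function(W, s, what) {
    if (is.null(W)) return(NULL)
    W <- as.matrix(W)
    if (any(W < 0)) stop(what, " weights must be >= 0")
    if (ncol(W) != length(s))
      stop("shape mismatch: ", what, " weights have ", ncol(W),
           " columns but ", length(s), " presynaptic activations")
    as.double(W %*% as.double(s))
  }
  gE <- one(weights_exc, s_pre_exc, "excitatory")
  gI <- one(weights_inh, s_pre_inh, "inhibitory")
  list(gE = gE %||% 0, gI = gI %||% 0)
}

#' Advance the online rate estimate by one step
#'
#' The rate estimate is an exponential filter of the spike train with time
#' constant `tau_r` and unit area: each spike adds `1000 / tau_r` Hz.
#'
#' @inheritParams step_synaptic_activation
#' @return the updated group.
#' @export
step_rate_estimate <- function(group, spikes = group$spikes, dt) {
  check_group(group)
  spikes <- as.integer(rep_len(spikes, group$n))
  group$r <- as.double(cpp_rate_step(group$r, spikes,
                                     group$params$tau_r, dt))
  group
}

#' @export
print.neuron_group <- function(x, ...) {
  cat("<neuron_group> ", x$n, " LIF neurons, mean v = ",
      sprintf("%.1f", mean(x$v)), " mV, mean rate = ",
      sprintf("%.1f", mean(x$r)), " Hz\n", sep = "")
  invisible(x)
}
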