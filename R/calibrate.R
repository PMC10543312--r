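# Calibration of the tonic drive that sets spontaneous VTA firing rates.
# The model treats the noise term as white current noise of fixed amplitude;
# the mean tonic current is then solved (by bisection on short simulations)
# so that an isolated noisy LIF population fires at the target rate.  The
# frozen numbers in flex_defaults() were obtained with this routine.

#' Mean firing rate of an isolated noisy LIF population
#'
#' Simulates `n` unconnected neurons with the given tonic current and noise
#' amplitude and returns the population mean rate from the spike count.
#'
#' @param tonic tonic current (pA).
#' @param sigma current-noise amplitude (pA sqrt(ms)).
#' @param gI_tonic constant inhibitory conductance (nS), e.g. from tonic
#'   GABAergic input.
#' @param n number of neurons.
#' @param duration simulated time (ms).
#' @param dt time step (ms).
#' @param params base [neuron_params()] (sigma/tonic fields overridden).
#' @return mean rate (Hz).
#' @export
tonic_rate <- function(tonic, sigma, gI_tonic = 0, n = 100,
                       duration = 5000, dt = 0.5,
                       params = neuron_params()) {
  params$tonic <- tonic
  params$sigma <- sigma
  g <- neuron_group(n, params)
  n_steps <- as.integer(round(duration / dt))
  gE <- rep(0, n); gI <- rep(gI_tonic, n)
  spikes <- 0
  for (i in seq_len(n_steps)) {
    g <- step_membrane(g, gE, gI, dt, noise = TRUE)
    spikes <- spikes + sum(g$spikes)
  }
  1000 * spikes / (n * duration)
}

#' Solve the tonic current for a target spontaneous rate
#'
#' Bisection on [tonic_rate()]; deterministic given `seed`.
#'
#' @param target_hz target population rate (Hz).
#' @param sigma current-noise amplitude (pA sqrt(ms)).
#' @param gI_tonic constant inhibitory conductance (nS).
#' @param lower,upper bracketing tonic currents (pA).
#' @param tol rate tolerance (Hz).
#' @param seed seed for the calibration noise stream.
#' @param ... passed to [tonic_rate()].
#' @return calibrated tonic current (pA).
#' @export
calibrate_tonic <- function(target_hz = 5, sigma = 220, gI_tonic = 0,
                            lower = 0, upper = 250, tol = 0.1,
                            seed = 1, ...) {
  with_seed(seed, {
    lo <- lower; hi <- upper
    for (i in 1:12) {
      mid <- (lo + hi) / 2
      r <- tonic_rate(mid, sigma, gI_tonic, ...)
      if (abs(r - target_hz) < tol) return(mid)
      if (r > target_hz) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  })
}
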