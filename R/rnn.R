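# Fixed random recurrent network as a candidate "universal" temporal basis:
# the demonstration that post-cue trajectories depend on stimulus history,
# so a fixed reservoir cannot provide a repeatable cue-relative time code.

#' Create a fixed random recurrent network
#'
#' Rate units with `tau du/dt = -u + W phi(u) + input(t)`; recurrent weights
#' are drawn once from a zero-mean normal with standard deviation
#' `g / sqrt(K)` (gain-scaled 1/K variance) and then frozen.  Each stimulus
#' is a unique normally distributed input vector applied as a 100 ms step.
#'
#' @param K number of units.
#' @param g recurrent gain; `g > 1` puts the network in the rich dynamical
#'   regime.
#' @param tau unit time constant (ms).
#' @param stimuli character vector of stimulus names to draw input vectors
#'   for.
#' @param input_scale amplitude of the stimulus input vectors.
#' @param seed integer seed for the weight and input draws.
#' @return object of class `fixed_rnn`.
#' @export
#' @examples
#' rnn <- fixed_rnn(K = 50, seed = 1)
#' rnn
fixed_rnn <- function(K = 500, g = 1.5, tau = 50,
                      stimuli = c("A", "B", "C"), input_scale = 1,
                      seed = NULL) {
  stopifnot(K >= 2, g >= 0, tau > 0)
  with_seed(seed, {
    W <- matrix(rnorm(K * K, 0, g / sqrt(K)), K, K)
    inputs <- lapply(stimuli, function(s) rnorm(K, 0, input_scale))
    names(inputs) <- stimuli
    structure(list(K = K, g = g, tau = tau, W = W, inputs = inputs,
                   phi = tanh),
              class = "fixed_rnn")
  })
}

#' @export
print.fixed_rnn <- function(x, ...) {
  cat("<fixed_rnn> ", x$K, " units, gain ", x$g, ", tau ", x$tau,
      " ms, stimuli: ", paste(names(x$inputs), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Simulate the fixed RNN for a stimulus sequence
#'
#' Forward-Euler integration; deterministic given the network and inputs
#' (no noise term), so identical sequences give identical trajectories.
#'
#' @param rnn a [fixed_rnn()].
#' @param sequence data.frame with columns `stimulus` and `onset` (ms);
#'   each stimulus is applied for `stim_duration` ms.
#' @param duration total simulated time (ms).
#' @param dt time step (ms).
#' @param stim_duration stimulus step length (ms).
#' @param u0 initial state (scalar or length-K vector).
#' @return matrix (time x K) of unit activities, with attribute `time`.
#' @export
simulate_rnn <- function(rnn, sequence, duration, dt = 1,
                         stim_duration = 100, u0 = 0) {
  stopifnot(inherits(rnn, "fixed_rnn"))
  if (nrow(sequence) &&
      any(sequence$onset < 0 | sequence$onset > duration))
    stop("stimulus onsets must lie within the simulated duration")
  bad <- setdiff(as.character(sequence$stimulus), names(rnn$inputs))
  if (length(bad)) stop("unknown stimulus '", bad[1], "'")
  n_steps <- as.integer(round(duration / dt))
  u <- rep_len(as.double(u0), rnn$K)
  out <- matrix(0, n_steps, rnn$K)
  tms <- seq_len(n_steps) * dt
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    inp <- rep(0, rnn$K)
    for (j in seq_len(nrow(sequence))) {
      on <- sequence$onset[j]
      if (t >= on && t < on + stim_duration)
        inp <- inp + rnn$inputs[[as.character(sequence$stimulus[j])]]
    }
    u <- u + dt / rnn$tau * (-u + rnn$W %*% rnn$phi(u) + inp)
    out[i, ] <- u
  }
  attr(out, "time") <- tms
  out
}

#' Shared-frame principal-component projection of trajectories
#'
#' Fits principal axes on the concatenation of all trajectories and returns
#' each trajectory projected into that common frame.
#'
#' @param trajectories list of (time x K) trajectory matrices.
#' @param n_components number of components.
#' @return list with `projections` (list of time x n_components matrices),
#'   `explained` (fraction of variance per component) and the `rotation`.
#' @export
project_pca <- function(trajectories, n_components = 2) {
  if (!is.list(trajectories)) trajectories <- list(trajectories)
  X <- do.call(rbind, trajectories)
  if (nrow(X) < 2) stop("need at least 2 time points")
  if (all(apply(X, 2, sd) < 1e-12))
    stop("degenerate (constant) trajectories: no principal axes")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  ctr <- pc$center
  list(projections = lapply(trajectories, function(tr)
         sweep(tr, 2, ctr) %*% rot),
       explained = ev[seq_len(n_components)], rotation = rot)
}

#' History dependence of post-cue trajectories
#'
#' Aligns two trajectories at a common event time and measures their
#' per-time-point state distance over the following window, normalized by
#' the mean state norm.  Identical histories give exactly zero; distinct
#' histories in the rich regime give divergence bounded away from zero.
#'
#' @param traj_a,traj_b trajectory matrices from [simulate_rnn()] (equal
#'   sampling).
#' @param align_at event time (ms) at which to align.
#' @param window length of the post-event window (ms).
#' @return list with `time`, `distance` (per time point), and `summary`
#'   (mean distance over the window / mean state norm).
#' @export
trajectory_divergence <- function(traj_a, traj_b, align_at, window = 1000) {
  ta <- attr(traj_a, "time"); tb <- attr(traj_b, "time")
  if (is.null(ta) || is.null(tb) || length(ta) != length(tb) ||
      ncol(traj_a) != ncol(traj_b))
    stop("misaligned trajectories: equal sampling and width required")
  keep <- ta >= align_at & ta <= align_at + window
  if (!any(keep)) stop("alignment window lies outside the trajectories")
  A <- traj_a[keep, , drop = FALSE]
  B <- traj_b[keep, , drop = FALSE]
  d <- sqrt(rowSums((A - B)^2))
  nrm <- mean(0.5 * (sqrt(rowSums(A^2)) + sqrt(rowSums(B^2))))
  list(time = ta[keep], distance = d,
       summary = if (nrm > 0) mean(d) / nrm else 0)
}
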