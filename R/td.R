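# Reference temporal-difference learners over a fixed temporal basis
# (complete serial compound or Gaussian microstimuli), used to contrast the
# spiking model's dopamine dynamics with classic RPE predictions: the
# backward-moving bump of TD(0), its absence under TD(lambda), and the
# conservation/discounting behavior of the per-trial integrated RPE.

#' Create a TD learner over a fixed temporal basis
#'
#' Time is tiled into bins; the cue triggers a chain of microstates (one per
#' post-cue bin).  The value function is the feature-weight inner product
#' and learning uses TD(lambda) with accumulating eligibility: `delta_t =
#' r_t + gamma V(t) - V(t-1)`, `e <- gamma lambda e + x_(t-1)`, `w <- w +
#' alpha delta e`.  `lambda = 0` recovers one-step TD(0).
#'
#' @param n_states number of post-cue microstates.
#' @param gamma discount factor in (0, 1].
#' @param lambda eligibility decay in \[0, 1\].
#' @param alpha learning rate.
#' @param basis `"csc"` (one-hot complete serial compound) or `"gaussian"`
#'   (overlapping Gaussian bumps over the post-cue bins).
#' @param bin bin width (ms), the analysis resolution.
#' @param sigma_bins Gaussian feature width in bins (`basis = "gaussian"`).
#' @return object of class `td_model`.
#' @export
#' @examples
#' m <- td_model(20, gamma = 1, lambda = 0)
#' m
td_model <- function(n_states, gamma = 1, lambda = 0.9, alpha = 0.1,
                     basis = c("csc", "gaussian"), bin = 50,
                     sigma_bins = 1) {
  basis <- match.arg(basis)
  stopifnot(n_states >= 1, gamma > 0, gamma <= 1, lambda >= 0, lambda <= 1,
            alpha > 0)
  feat <- if (basis == "csc") diag(n_states)
  else {
    centers <- seq_len(n_states)
    t(vapply(centers, function(k)
      exp(-(seq_len(n_states) - k)^2 / (2 * sigma_bins^2)),
      numeric(n_states)))
  }
  structure(list(w = rep(0, n_states), e = rep(0, n_states),
                 gamma = gamma, lambda = lambda, alpha = alpha,
                 basis = basis, features = feat, bin = bin,
                 n_states = n_states),
            class = "td_model")
}

# feature vector for post-cue state k (1-based); zero vector outside the
# chain (pre-cue or beyond the last microstate)
td_features <- function(model, k) {
  if (is.na(k) || k < 1 || k > model$n_states) rep(0, model$n_states)
  else model$features[k, ]
}

#' One TD update step
#'
#' @param model a [td_model()].
#' @param x_prev,x_curr feature vectors of the previous and current bin.
#' @param reward reward received in the current bin.
#' @return list with the RPE `delta` and the updated `model`.
#' @export
td_step <- function(model, x_prev, x_curr, reward = 0) {
  v_prev <- sum(model$w * x_prev)
  v_curr <- sum(model$w * x_curr)
  delta <- reward + model$gamma * v_curr - v_prev
  model$e <- model$gamma * model$lambda * model$e + x_prev
  model$w <- model$w + model$alpha * delta * model$e
  list(delta = delta, model = model)
}

#' Run a TD learner over repeated conditioning trials
#'
#' Each trial has one cue and one reward.  The eligibility vector resets at
#' trial start; weights persist.
#'
#' @param model a [td_model()].
#' @param n_trials number of trials (0 gives an empty RPE matrix).
#' @param cs_bin,us_bin cue and reward bins (1-based, `cs_bin < us_bin`).
#' @param n_bins bins per trial.
#' @param reward reward magnitude.
#' @return list with `rpe` (trials x bins matrix of RPEs; the entry in bin
#'   t is the prediction error on arriving in bin t) and the updated
#'   `model`.
#' @export
#' @examples
#' out <- run_td_session(td_model(20, lambda = 0), n_trials = 5,
#'                       cs_bin = 3, us_bin = 13, n_bins = 20)
#' dim(out$rpe)
run_td_session <- function(model, n_trials, cs_bin = 3, us_bin = 23,
                           n_bins = 32, reward = 1) {
  stopifnot(inherits(model, "td_model"), cs_bin < us_bin,
            us_bin <= n_bins)
  rpe <- matrix(0, n_trials, n_bins)
  if (n_trials < 1)
    return(list(rpe = rpe, model = model))
  for (tr in seq_len(n_trials)) {
    model$e <- rep(0, model$n_states)
    for (t in seq_len(n_bins)) {
      k_prev <- (t - 1) - cs_bin + 1   # post-cue state index of bin t-1
      k_curr <- t - cs_bin + 1
      x_prev <- td_features(model, k_prev)
      x_curr <- td_features(model, k_curr)
      r <- if (t == us_bin) reward else 0
      out <- td_step(model, x_prev, x_curr, r)
      rpe[tr, t] <- out$delta
      model <- out$model
    }
  }
  list(rpe = rpe, model = model)
}

#' Per-trial integrated RPE
#'
#' Row sums of a trials-by-bins RPE matrix: the total prediction-error
#' signal emitted in each trial.  For an undiscounted learner over a
#' one-hot basis this quantity telescopes to the delivered reward and is
#' conserved across training; with discounting it decreases as learning
#' progresses, and it never exceeds the total of the first unexpected
#' reward.
#'
#' @param rpe_matrix trials x bins matrix from [run_td_session()].
#' @return numeric vector of per-trial totals.
#' @export
integrated_rpe <- function(rpe_matrix) {
  if (is.null(dim(rpe_matrix))) rpe_matrix <- matrix(rpe_matrix, nrow = 1)
  rowSums(rpe_matrix)
}

#' @export
print.td_model <- function(x, ...) {
  cat("<td_model> ", x$n_states, " microstates (", x$basis,
      "), gamma = ", x$gamma, ", lambda = ", x$lambda,
      ", alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' @export
coef.td_model <- function(object, ...) object$w
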