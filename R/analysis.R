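# Quantitative readouts: spike-count auROC maps, per-trial integrated
# reinforcement, response magnitudes at cue/reward windows, and the
# learning-stage classifier for sequential conditioning.

#' Area under the ROC curve for two spike-count samples
#'
#' Sweeps an integer criterion from zero to the maximum count and traces
#' P(active > criterion) against P(baseline > criterion); the area under
#' the resulting curve (trapezoidal rule, endpoints (0,0) and (1,1)
#' included) measures the discriminability of the two count distributions.
#' 0.5 means indistinguishable, 1 a maximally discriminable increase, 0 a
#' maximally discriminable decrease.
#'
#' @param baseline_counts,active_counts non-negative integer spike counts
#'   (one per trial), non-empty.
#' @return auROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0, 1, 2), c(5, 6, 7))  # 1
#' auroc(c(3, 3, 3), c(3, 3, 3))  # 0.5
auroc <- function(baseline_counts, active_counts) {
  if (!length(baseline_counts) || !length(active_counts))
    stop("both samples must be non-empty")
  crit <- seq(-1L, max(baseline_counts, active_counts, 0L))
  x <- vapply(crit, function(cr) mean(baseline_counts > cr), numeric(1))
  y <- vapply(crit, function(cr) mean(active_counts > cr), numeric(1))
  # x descends from 1 to 0 along the sweep; trapezoid in that order
  sum((x[-length(x)] - x[-1]) * (y[-length(y)] + y[-1]) / 2)
}

#' Per-neuron, per-bin auROC map between two conditions
#'
#' For every neuron and time bin, compares the spike-count distribution
#' across the condition trials with the distribution across the baseline
#' trials (same bin), giving a neurons x bins map of discriminability.
#'
#' @param baseline_recordings,active_recordings lists of `flex_trial`
#'   recordings (equal trial counts per condition recommended; the
#'   reference analyses use 15-25 trials) carrying binned counts for
#'   `group`.
#' @param group population whose counts are compared (default `"da"`).
#' @return object of class `auroc_map`: a neurons x bins matrix in
#'   \[0, 1\] with attributes `bin_width` and `group`.
#' @export
auroc_map <- function(baseline_recordings, active_recordings,
                      group = "da") {
  get_counts <- function(recs) {
    lapply(recs, function(r) {
      if (is.null(r$counts[[group]]))
        stop("recording lacks binned counts for group '", group, "'")
      r$counts[[group]]
    })
  }
  cb <- get_counts(baseline_recordings)
  ca <- get_counts(active_recordings)
  nb <- min(vapply(c(cb, ca), ncol, integer(1)))
  n <- nrow(cb[[1]])
  out <- matrix(NA_real_, n, nb)
  for (j in seq_len(nb)) {
    base_j <- vapply(cb, function(m) m[, j], numeric(n))  # n x trials
    act_j <- vapply(ca, function(m) m[, j], numeric(n))
    for (i in seq_len(n))
      out[i, j] <- auroc(base_j[i, ], act_j[i, ])
  }
  structure(out, class = "auroc_map",
            bin_width = baseline_recordings[[1]]$bin_width, group = group)
}

#' @export
print.auroc_map <- function(x, ...) {
  cat("<auroc_map> ", nrow(x), " neurons x ", ncol(x), " bins (",
      attr(x, "bin_width"), " ms), group '", attr(x, "group"),
      "', range ", sprintf("%.2f-%.2f", min(x), max(x)), "\n", sep = "")
  invisible(x)
}

#' Rectangle-rule integral of a sampled signal
#'
#' @param signal sampled time series.
#' @param dt sampling interval.
#' @return `sum(signal) * dt`; linear in the signal.
#' @export
#' @examples
#' trial_integral(rep(2, 10), dt = 0.5)  # 10
trial_integral <- function(signal, dt) {
  sum(as.double(signal)) * dt
}

#' Per-trial integrated reinforcement of a session
#'
#' @param history a `flex_history`.
#' @param positive_only integrate `max(D, 0)` instead of the signed signal.
#' @return numeric vector, one integral per trial (Hz ms).
#' @export
session_integrals <- function(history, positive_only = FALSE) {
  vapply(history$trials, function(tr) {
    d <- if (positive_only) pmax(tr$D, 0) else tr$D
    trial_integral(d, tr$record_every)
  }, numeric(1))
}

#' Cue- and reward-locked dopamine response magnitudes
#'
#' Mean dopamine population rate in excess of baseline within the given
#' windows.
#'
#' @param recording a `flex_trial`.
#' @param windows named list of `c(start, end)` windows (ms), e.g.
#'   `list(CS = c(100, 350), US = c(1100, 1350))`.
#' @param r0 baseline rate; defaults to the recording's.
#' @return named numeric vector of rate excesses (Hz).
#' @export
response_magnitudes <- function(recording, windows, r0 = recording$r0) {
  stopifnot(inherits(recording, "flex_trial"))
  rda <- recording$pop_rates[, "da"]
  t <- recording$time
  vapply(windows, function(w) {
    keep <- t >= w[1] & t < w[2]
    if (!any(keep)) stop("window outside the recorded trial")
    mean(rda[keep]) - r0
  }, numeric(1))
}

#' Classify the learning stage of each sequential-conditioning trial
#'
#' Labels every trial by the sign pattern of the dopamine responses at the
#' first cue, second cue and reward: (0,0,+) initialization; (+,+,+)
#' acquisition; (+,+,0) reward_depression; (+,0,0) serial_transfer; any
#' other pattern is labeled transitional rather than misassigned.  A
#' response counts as present when it exceeds `threshold_frac` of the
#' trial-1 reward response.
#'
#' @param history a `flex_history` from a sequential-conditioning session.
#' @param cs1_onset,cs2_onset,us_onset event onsets (ms); defaults from the
#'   session metadata.
#' @param window response-window length after each onset (ms).
#' @param threshold_frac fraction of the trial-1 reward response used as
#'   the presence threshold.
#' @return factor of per-trial stage labels, with the response matrix in
#'   attribute `responses`.
#' @export
stage_classifier <- function(history, cs1_onset = NULL, cs2_onset = NULL,
                             us_onset = NULL, window = 250,
                             threshold_frac = 0.25) {
  meta <- history$session$meta
  cs1_onset <- cs1_onset %||% meta$cs1_onset
  cs2_onset <- cs2_onset %||% meta$cs2_onset
  us_onset <- us_onset %||% meta$us_onset
  if (is.null(cs1_onset) || is.null(cs2_onset) || is.null(us_onset))
    stop("event onsets missing: give cs1_onset/cs2_onset/us_onset")
  wins <- list(cs1 = c(cs1_onset, cs1_onset + window),
               cs2 = c(cs2_onset, cs2_onset + window),
               us = c(us_onset, us_onset + window))
  resp <- t(vapply(history$trials, response_magnitudes, numeric(3),
                   windows = wins))
  thr <- threshold_frac * resp[1, "us"]
  if (!is.finite(thr) || thr <= 0)
    stop("trial-1 reward response is not positive; cannot set threshold")
  on <- resp > thr
  lab <- apply(on, 1, function(p) {
    if (!p[1] && !p[2] && p[3]) "initialization"
    else if (p[1] && p[2] && p[3]) "acquisition"
    else if (p[1] && p[2] && !p[3]) "reward_depression"
    else if (p[1] && !p[2] && !p[3]) "serial_transfer"
    else "transitional"
  })
  structure(factor(lab, levels = c("initialization", "acquisition",
                                   "reward_depression", "serial_transfer",
                                   "transitional")),
            responses = resp)
}

#' Time of a population's peak response from binned spike counts
#'
#' Returns the center of the 50 ms (or configured) bin with the highest
#' summed spike count across the population.  Unlike the online rate
#' estimate, binned counts carry no causal-filter lag, so this is the
#' preferred peak-time estimator for event-locked responses.
#'
#' @param recording a `flex_trial` carrying binned counts for `group`.
#' @param group population name (default `"da"`).
#' @return peak time (ms, bin center).
#' @export
response_peak_time <- function(recording, group = "da") {
  stopifnot(inherits(recording, "flex_trial"))
  cnt <- recording$counts[[group]]
  if (is.null(cnt))
    stop("recording lacks binned counts for group '", group, "'")
  tot <- colSums(cnt)
  (which.max(tot) - 0.5) * recording$bin_width
}

#' Trial index at which a response trajectory crosses a level
#'
#' Helper for learning-order analyses: first trial at which `x` rises above
#' (`direction = "up"`) or falls below (`direction = "down"`) `level`,
#' after median smoothing.
#'
#' @param x per-trial response values.
#' @param level crossing level.
#' @param direction `"up"` or `"down"`.
#' @param k odd smoothing window (trials).
#' @return trial index, or `NA` if never crossed.
#' @export
crossing_trial <- function(x, level, direction = c("up", "down"), k = 3) {
  direction <- match.arg(direction)
  xs <- stats::runmed(x, k)
  hit <- if (direction == "up") which(xs >= level) else which(xs <= level)
  if (length(hit)) hit[1] else NA_integer_
}
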