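# Event-schedule generators for the conditioning paradigms and the session
# runner that executes them trial by trial (weights persist across trials,
# eligibility traces and dynamic state reset at each trial start).

#' Construct a single-trial event schedule
#'
#' @param trial_length trial duration (ms).
#' @param stimuli data.frame with columns `stimulus`, `onset`, `duration`,
#'   `magnitude` (cues); may be `NULL`.
#' @param rewards data.frame with columns `onset`, `duration`, `magnitude`;
#'   may be `NULL`.
#' @param learning logical; plasticity enabled on this trial.
#' @return object of class `event_schedule`.
#' @export
event_schedule <- function(trial_length, stimuli = NULL, rewards = NULL,
                           learning = TRUE) {
  ev <- NULL
  if (!is.null(stimuli) && nrow(stimuli)) {
    stopifnot(all(c("stimulus", "onset", "duration", "magnitude") %in%
                    names(stimuli)))
    ev <- stimuli
  }
  if (!is.null(rewards) && nrow(rewards)) {
    stopifnot(all(c("onset", "duration", "magnitude") %in% names(rewards)))
    ev <- rbind(ev, data.frame(stimulus = "us", onset = rewards$onset,
                               duration = rewards$duration,
                               magnitude = rewards$magnitude))
  }
  if (!is.null(ev)) {
    if (any(ev$onset < 0)) stop("onsets must be >= 0")
    if (any(ev$magnitude < 0)) stop("magnitudes must be >= 0")
    if (any(ev$onset + ev$duration > trial_length))
      stop("all onsets + durations must be <= trial_length")
  }
  structure(list(trial_length = trial_length,
                 events = ev, learning = isTRUE(learning)),
            class = "event_schedule")
}

new_session <- function(trials, protocol, meta = list()) {
  if (!length(trials)) stop("empty session: no trials")
  structure(list(trials = trials, protocol = protocol, meta = meta),
            class = "flex_session")
}

#' @export
print.flex_session <- function(x, ...) {
  cat("<flex_session> ", length(x$trials), " trials, protocol: ",
      x$protocol, "\n", sep = "")
  invisible(x)
}

#' @export
length.flex_session <- function(x) length(x$trials)

#' @export
c.flex_session <- function(...) {
  parts <- list(...)
  new_session(unlist(lapply(parts, `[[`, "trials"), recursive = FALSE),
              paste(vapply(parts, `[[`, "", "protocol"), collapse = "+"))
}

#' Single-cue trace conditioning protocol
#'
#' Identical trials pairing one cue with one delayed reward.  Defaults:
#' 40 trials, cue onset 100 ms, reward onset 1100 ms.
#'
#' @param n_trials number of training trials (> 0).
#' @param cs_onset,us_onset cue and reward onsets (ms), `cs_onset <
#'   us_onset`.
#' @param cs_duration,us_duration event durations (ms).
#' @param magnitude reward magnitude (maps linearly to the reward input
#'   conductance).
#' @param trial_length trial duration (ms).
#' @param stimulus cue identifier (must name a column of the network).
#' @return a `flex_session`.
#' @export
#' @examples
#' s <- trace_conditioning(n_trials = 3)
#' length(s)
trace_conditioning <- function(n_trials = 40, cs_onset = 100,
                               us_onset = 1100, cs_duration = 150,
                               us_duration = 50, magnitude = 1,
                               trial_length = 1600, stimulus = "cs1") {
  if (n_trials < 1) stop("empty session: n_trials must be >= 1")
  if (!(cs_onset < us_onset)) stop("need cs_onset < us_onset")
  if (us_onset + us_duration > trial_length)
    stop("need us_onset + us_duration <= trial_length")
  trial <- event_schedule(
    trial_length,
    stimuli = data.frame(stimulus = stimulus, onset = cs_onset,
                         duration = cs_duration, magnitude = 1),
    rewards = data.frame(onset = us_onset, duration = us_duration,
                         magnitude = magnitude))
  new_session(rep(list(trial), n_trials), "trace",
              meta = list(cs_onset = cs_onset, us_onset = us_onset,
                          stimulus = stimulus))
}

#' Sequential conditioning protocol (two cues, one reward)
#'
#' Defaults: cue 1 at 100 ms, cue 2 at 800 ms, reward at 1500 ms.
#'
#' @param n_trials number of trials.
#' @param cs1_onset,cs2_onset,us_onset event onsets (ms), strictly ordered.
#' @param cs_duration,us_duration event durations (ms).
#' @param magnitude reward magnitude.
#' @param trial_length trial duration (ms).
#' @param stimuli identifiers of the two cue columns.
#' @param drop_cs2 omit cue 2 (post-training probe variant).
#' @return a `flex_session`.
#' @export
sequential_conditioning <- function(n_trials = 70, cs1_onset = 100,
                                    cs2_onset = 800, us_onset = 1500,
                                    cs_duration = 150, us_duration = 50,
                                    magnitude = 1, trial_length = 2000,
                                    stimuli = c("cs1", "cs2"),
                                    drop_cs2 = FALSE) {
  if (n_trials < 1) stop("empty session: n_trials must be >= 1")
  if (!(cs1_onset < cs2_onset && cs2_onset < us_onset))
    stop("need cs1_onset < cs2_onset < us_onset")
  cues <- data.frame(stimulus = stimuli,
                     onset = c(cs1_onset, cs2_onset),
                     duration = cs_duration, magnitude = 1)
  if (drop_cs2) cues <- cues[1, ]
  trial <- event_schedule(
    trial_length, stimuli = cues,
    rewards = data.frame(onset = us_onset, duration = us_duration,
                         magnitude = magnitude))
  new_session(rep(list(trial), n_trials), "sequential",
              meta = list(cs1_onset = cs1_onset, cs2_onset = cs2_onset,
                          us_onset = us_onset, stimuli = stimuli))
}

#' Reward omission and extinction protocols
#'
#' Appends cue-only (reward-free) trials to a trained session's schedule:
#' a single omission probe, or a block of extinction trials.
#'
#' @param trained_session the session the network was trained on (its last
#'   trial provides the cue layout).
#' @param n_omit number of cue-only trials for `mode =
#'   "repeated_extinction"` (> 0).
#' @param mode `"single_omission"` or `"repeated_extinction"`.
#' @return a `flex_session` of cue-only trials.
#' @export
omission_extinction <- function(trained_session, n_omit = 1,
                                mode = c("single_omission",
                                         "repeated_extinction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trained_session, "flex_session"))
  last <- trained_session$trials[[length(trained_session$trials)]]
  ev <- last$events
  cues <- ev[as.character(ev$stimulus) != "us", , drop = FALSE]
  probe <- event_schedule(last$trial_length, stimuli = cues,
                          rewards = NULL)
  n <- if (mode == "single_omission") 1L else as.integer(n_omit)
  if (n <= 0) stop("n_omit must be > 0 for repeated_extinction")
  new_session(rep(list(probe), n),
              if (mode == "single_omission") "omission" else "extinction")
}

#' Blocking / unblocking protocol
#'
#' Phase 1: single-cue trace conditioning on cue 1.  Phase 2: a second cue
#' is inserted between cue 1 and the reward, with the reward magnitude
#' multiplied by `reward_boost`.  `reward_boost = 1` probes blocking (the
#' inserted cue should not become reward predictive); `reward_boost > 1`
#' probes unblocking.
#'
#' @param phase1_trials,phase2_trials trial counts for the two phases.
#' @param reward_boost reward-magnitude multiplier in phase 2 (>= 1).
#' @param cs1_onset,cs2_onset,us_onset onsets (ms); cue 2 sits between cue 1
#'   and the unchanged reward time.
#' @param trial_length trial duration (ms).
#' @param stimuli identifiers of the two cue columns.
#' @return a `flex_session` containing both phases in order.
#' @export
blocking_unblocking <- function(phase1_trials = 40, phase2_trials = 25,
                                reward_boost = 1, cs1_onset = 100,
                                cs2_onset = 600, us_onset = 1100,
                                trial_length = 1600,
                                stimuli = c("cs1", "cs2")) {
  if (reward_boost < 1) stop("reward_boost must be >= 1")
  p1 <- trace_conditioning(phase1_trials, cs_onset = cs1_onset,
                           us_onset = us_onset,
                           trial_length = trial_length,
                           stimulus = stimuli[1])
  if (phase2_trials < 1) return(p1)
  p2 <- sequential_conditioning(phase2_trials, cs1_onset = cs1_onset,
                                cs2_onset = cs2_onset, us_onset = us_onset,
                                magnitude = reward_boost,
                                trial_length = trial_length,
                                stimuli = stimuli)
  out <- c(p1, p2)
  out$protocol <- if (reward_boost > 1) "unblocking" else "blocking"
  out$meta <- list(phase1_trials = phase1_trials,
                   phase2_trials = phase2_trials,
                   reward_boost = reward_boost, cs1_onset = cs1_onset,
                   cs2_onset = cs2_onset, us_onset = us_onset)
  out
}

#' Reward-only baseline block
#'
#' Trials with the reward alone and (by default) learning disabled on all
#' pathways; used as the pre-learning comparison block.
#'
#' @param n_trials number of trials.
#' @param us_onset,us_duration reward onset and duration (ms).
#' @param magnitude reward magnitude.
#' @param trial_length trial duration (ms).
#' @param learning enable plasticity during the block.
#' @return a `flex_session`.
#' @export
us_only_session <- function(n_trials = 100, us_onset = 1100,
                            us_duration = 50, magnitude = 1,
                            trial_length = 1600, learning = FALSE) {
  if (n_trials < 1) stop("empty session: n_trials must be >= 1")
  trial <- event_schedule(
    trial_length,
    rewards = data.frame(onset = us_onset, duration = us_duration,
                         magnitude = magnitude),
    learning = learning)
  new_session(rep(list(trial), n_trials), "us_only")
}

#' Baseline (no-stimulus) block
#'
#' Event-free trials at spontaneous activity; the baseline condition of the
#' auROC analyses.
#'
#' @inheritParams us_only_session
#' @return a `flex_session`.
#' @export
baseline_session <- function(n_trials = 25, trial_length = 1600) {
  trial <- event_schedule(trial_length, learning = FALSE)
  new_session(rep(list(trial), n_trials), "baseline")
}

#' Run a session trial by trial
#'
#' Executes the schedule in order.  Weights persist across trials;
#' eligibility traces and dynamic state are reset at each trial start.
#'
#' @param net a [flex_network()].
#' @param session a `flex_session`.
#' @param seed optional seed for the simulation noise stream.
#' @param learning master switch; `FALSE` disables plasticity for the whole
#'   session regardless of per-trial flags.
#' @param record_every,bin_width,bin_groups recording options, see
#'   [run_trial()].
#' @param progress print a line every `progress` trials (0 = quiet).
#' @return object of class `flex_history`: per-trial recordings, the
#'   mean-weight trajectory of every plastic pathway (data.frame `weights`
#'   with columns trial, projection, mean_w), and the final network.
#' @export
#' @examples
#' \donttest{
#' net <- flex_network("cs1", seed = 1)
#' hist <- run_session(net, trace_conditioning(n_trials = 2), seed = 1)
#' hist
#' }
run_session <- function(net, session, seed = NULL, learning = TRUE,
                        record_every = 1, bin_width = 50,
                        bin_groups = c("da", "gaba"), progress = 0) {
  stopifnot(inherits(net, "flex_network"), inherits(session, "flex_session"))
  for (tr in session$trials) {
    ev <- tr$events
    if (!is.null(ev)) {
      ids <- setdiff(unique(as.character(ev$stimulus)), "us")
      bad <- setdiff(ids, net$spec$stimuli)
      if (length(bad))
        stop("unknown stimulus id '", bad[1], "' in session schedule")
    }
  }
  with_seed(seed, {
    n <- length(session$trials)
    recs <- vector("list", n)
    wtab <- vector("list", n)
    for (i in seq_len(n)) {
      out <- run_trial(net, session$trials[[i]], learning = learning,
                       record_every = record_every, bin_width = bin_width,
                       bin_groups = bin_groups)
      net <- out$net
      recs[[i]] <- out$recording
      w <- coef(net)
      wtab[[i]] <- data.frame(trial = i, projection = names(w),
                              mean_w = unname(w))
      if (progress > 0 && i %% progress == 0)
        message("trial ", i, "/", n)
    }
    structure(list(trials = recs, weights = do.call(rbind, wtab),
                   net = net, session = session),
              class = "flex_history")
  })
}

#' @export
print.flex_history <- function(x, ...) {
  cat("<flex_history> ", length(x$trials), " trials (protocol: ",
      x$session$protocol, ")\n", sep = "")
  w <- coef(x$net)
  cat("  final mean weights: ",
      paste(sprintf("%s=%.4f", names(w), w), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.flex_history <- function(x, what = c("weights", "dopamine"), ...) {
  what <- match.arg(what)
  if (what == "weights") {
    w <- x$weights
    pjs <- unique(w$projection)
    graphics::matplot(
      do.call(cbind, lapply(pjs, function(p) w$mean_w[w$projection == p])),
      type = "l", lty = 1, xlab = "trial", ylab = "mean weight (nS)", ...)
    graphics::legend("topleft", legend = pjs, col = seq_along(pjs),
                     lty = 1, cex = 0.7)
  } else {
    D <- vapply(x$trials, function(tr) trial_integral(tr$D,
      tr$record_every), numeric(1))
    graphics::plot(D, type = "b", xlab = "trial",
                   ylab = "integrated D(t) (Hz ms)", ...)
  }
  invisible(x)
}
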