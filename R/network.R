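# Full model assembly: per-stimulus cortical columns (Timer, Inhibitory,
# Messenger populations plus a cue-relay population) and a reward module
# (dopaminergic and GABAergic populations), with fixed intra-column wiring
# and three plastic pathways: Timer->Timer recurrence (two-trace rule, gated
# cortical Hebbian term), cue->DA (two-trace rule), Messenger->GABA
# (dopamine-modulated Hebbian rule).

RULE_CODES <- c(fixed = 0L, dttl_vta = 1L, dttl_pfc = 2L, da_hebb = 3L,
                dttl_pfc_scalar = 4L)

#' Default structural and learning parameters of the model
#'
#' Returns the full list of tunable parameters: population sizes, neuron
#' parameters per population class, connection strengths (as the total
#' input conductance per postsynaptic neuron at full presynaptic
#' activation, nS), sparseness and initialization of the plastic pathways,
#' eligibility-trace parameters and learning rates.  Any entry can be
#' overridden through the `config` argument of [flex_network()].
#'
#' @return nested named list of defaults.
#' @export
flex_defaults <- function() {
  list(
    n = 100,            # neurons per cortical subpopulation
    n_vta = 100,        # neurons per VTA population (DA and GABA each)
    dt = 0.5,           # integration step, ms
    r0 = 5,             # DA baseline rate, Hz
    theta = 1,          # neutral half-width of the reinforcement, Hz
    warm_ms = 300,      # unrecorded settling time before each trial, ms
    stim_amp = 8,       # external drive per unit cue magnitude, nS
    us_amp = 7,         # external drive per unit reward magnitude, nS
    # tonic drive (pA) and current noise (pA sqrt(ms)) fixed by the
    # baseline-rate calibration (see calibrate_tonic and the vignette)
    vta = list(sigma = 220, tonic_da = 175, tonic_gaba = 140.6),
    pfc = list(sigma = 80, tonic = 0, timer_tonic_spread = 200,
               inh_tonic = 60, msg_tonic = 100),
    conn = list(
      ct = list(wtot = 12, p = 1,    jitter = 0.3),  # cue -> Timer (fast)
      ti = list(wtot = 50, p = 1,    jitter = 0.3),  # Timer -> Inh (fast)
      tm = list(wtot = 18, p = 1,    jitter = 0.3),  # Timer -> Msg (slow)
      im = list(wtot = 150, p = 1,   jitter = 0.3),  # Inh -> Msg (inhibitory)
      ud = list(wtot = 10, p = 0.15, jitter = 0.5),  # US -> DA (fixed)
      gd = list(wtot = 3.66, p = 1,  jitter = 0.3),  # GABA -> DA (inhibitory, slow)
      tt = list(w0 = 4.5, wmax = 9, p = 1, jitter = 0.1,   # Timer recurrence
                eta = 1.8e-5, alpha = 8,
                trace = trace_params(tau_d = 200, tmax_d = 1.3)),
      cd = list(w0 = 0.02, wmax = 8, p = 0.15, jitter = 0.5, # cue -> DA
                eta = 3e-5,
                trace = trace_params(eta_p = 0.0075, tmax_d = 1.15)),
      mg = list(w0 = 0, wmax = 40, p = 1, jitter = 0.3,      # Msg -> GABA
                eta = 1.2e-7)
    )
  )
}

#' Declare the model architecture
#'
#' @param stimuli character vector of stimulus (cue) identifiers; one
#'   cortical column is built per stimulus.  Must be non-empty.
#' @param n neurons per cortical subpopulation.
#' @param n_vta neurons per VTA population.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(stimuli, n = 100, n_vta = 100) {
  if (length(stimuli) < 1)
    stop("at least one stimulus column is required")
  stimuli <- as.character(stimuli)
  if (anyDuplicated(stimuli)) stop("stimulus ids must be unique")
  if (any(stimuli == "us")) stop("'us' is reserved for the reward channel")
  structure(list(stimuli = stimuli, n = as.integer(n),
                 n_vta = as.integer(n_vta)),
            class = "network_spec")
}

# sparse non-negative weight matrix with log-normal heterogeneity whose
# expected row sum is `wtot`
make_weights <- function(n_post, n_pre, wtot, p = 1, jitter = 0.3) {
  mask <- if (p < 1) matrix(rbinom(n_post * n_pre, 1, p), n_post) else 1
  mult <- matrix(rlnorm(n_post * n_pre, -jitter^2 / 2, jitter), n_post)
  (wtot / (n_pre * p)) * mult * mask
}

#' Build the full network
#'
#' Assembles the model of one or more cue-specific cortical columns plus the
#' shared reward module.  Construction is deterministic given `seed`.
#'
#' @param stimuli stimulus identifiers (one column each), or a
#'   [network_spec()] object.
#' @param n,n_vta population sizes (ignored when `stimuli` is a spec).
#' @param seed integer seed for the weight draws; `NULL` uses the ambient
#'   random stream.
#' @param config list of overrides merged into [flex_defaults()].
#' @return object of class `flex_network` with named populations
#'   (`cs_<id>`, `timer_<id>`, `inh_<id>`, `msg_<id>` per column, plus
#'   `us`, `da`, `gaba`), realized projections and dynamic state.
#' @export
#' @examples
#' net <- flex_network("cue", seed = 1)
#' net
flex_network <- function(stimuli = "cs1", n = 100, n_vta = 100,
                         seed = NULL, config = list()) {
  spec <- if (inherits(stimuli, "network_spec")) stimuli
          else network_spec(stimuli, n, n_vta)
  cfg <- modifyList(flex_defaults(), config)
  cfg$n <- spec$n; cfg$n_vta <- spec$n_vta

  with_seed(seed, {
    p_pfc <- neuron_params(sigma = cfg$pfc$sigma, tonic = cfg$pfc$tonic)
    p_da <- neuron_params(sigma = cfg$vta$sigma, tonic = cfg$vta$tonic_da)
    p_gaba <- neuron_params(sigma = cfg$vta$sigma, tonic = cfg$vta$tonic_gaba)

    groups <- list()
    for (st in spec$stimuli) {
      groups[[paste0("cs_", st)]] <- list(n = cfg$n, params = p_pfc)
      # Timers carry a spread of intrinsic excitabilities, so as the slow
      # recurrent drive decays the population sheds neurons progressively
      # and turns off at a weight-dependent, largely deterministic time
      # the ladder is evenly spaced, not sampled: random draws let the tail
      # of the distribution reshape the duration-vs-weight map from build
      # to build, while the mechanism only needs the spread itself
      groups[[paste0("timer_", st)]] <- list(
        n = cfg$n, params = p_pfc,
        tonic_extra = seq(-cfg$pfc$timer_tonic_spread,
                          cfg$pfc$timer_tonic_spread,
                          length.out = cfg$n))
      # Inh sits close to threshold so it tracks Timer activity down to low
      # rates (keeping Messengers gated through the graded decay); Msg gets
      # a smaller boost so the late slow-channel drive can still fire it
      p_inh <- p_pfc; p_inh$tonic <- cfg$pfc$inh_tonic
      p_msg <- p_pfc; p_msg$tonic <- cfg$pfc$msg_tonic
      groups[[paste0("inh_", st)]] <- list(n = cfg$n, params = p_inh)
      groups[[paste0("msg_", st)]] <- list(n = cfg$n, params = p_msg)
    }
    groups[["us"]] <- list(n = cfg$n, params = p_pfc)
    groups[["da"]] <- list(n = cfg$n_vta, params = p_da)
    groups[["gaba"]] <- list(n = cfg$n_vta, params = p_gaba)

    cn <- cfg$conn
    fixed <- function(src, tgt, cp, inhibitory = FALSE, slow = FALSE)
      list(src = src, tgt = tgt, inhibitory = inhibitory, use_slow = slow,
           rule = RULE_CODES[["fixed"]],
           W = make_weights(groups[[tgt]]$n, groups[[src]]$n,
                            cp$wtot, cp$p, cp$jitter))
    plastic <- function(src, tgt, cp, rule, slow = FALSE) {
      np_ <- groups[[tgt]]$n; npre <- groups[[src]]$n
      tr <- cp$trace %||% trace_params()
      scalar <- rule == "dttl_pfc_scalar"
      list(src = src, tgt = tgt, inhibitory = FALSE, use_slow = slow,
           rule = RULE_CODES[[rule]],
           W = make_weights(np_, npre, cp$w0, cp$p, cp$jitter),
           eta = cp$eta, wmax = cp$wmax / (npre * cp$p),
           alpha = cp$alpha %||% 0,
           eta_p = tr$eta_p, eta_d = tr$eta_d,
           tau_p = tr$tau_p, tau_d = tr$tau_d,
           tmax_p = tr$tmax_p, tmax_d = tr$tmax_d,
           Tp = matrix(0, if (scalar) 1 else np_, if (scalar) 1 else npre),
           Td = matrix(0, if (scalar) 1 else np_, if (scalar) 1 else npre))
    }

    proj <- list()
    for (st in spec$stimuli) {
      cs <- paste0("cs_", st); ti <- paste0("timer_", st)
      ih <- paste0("inh_", st); mg <- paste0("msg_", st)
      proj[[paste0("ct_", st)]] <- fixed(cs, ti, cn$ct)
      proj[[paste0("ti_", st)]] <- fixed(ti, ih, cn$ti)
      proj[[paste0("tm_", st)]] <- fixed(ti, mg, cn$tm, slow = TRUE)
      proj[[paste0("im_", st)]] <- fixed(ih, mg, cn$im, inhibitory = TRUE)
      proj[[paste0("tt_", st)]] <- plastic(ti, ti, cn$tt,
                                           "dttl_pfc_scalar", slow = TRUE)
      proj[[paste0("cd_", st)]] <- plastic(cs, "da", cn$cd, "dttl_vta")
      proj[[paste0("mg_", st)]] <- plastic(mg, "gaba", cn$mg, "da_hebb")
    }
    proj[["ud"]] <- fixed("us", "da", cn$ud)
    # GABA acts on DA through the slow channel (GABA-B-like kinetics);
    # the ~100 ms lag places the learned reward-locked inhibition at the
    # reward rather than at the slightly earlier Messenger burst
    proj[["gd"]] <- fixed("gaba", "da", cn$gd, inhibitory = TRUE,
                          slow = TRUE)

    net <- structure(list(
      spec = spec, config = cfg, groups = groups, projections = proj,
      dt = cfg$dt, r0 = cfg$r0, theta = cfg$theta, seed = seed
    ), class = "flex_network")
    reset_state(net)
  })
}

#' Reset the dynamic state of a network
#'
#' Membrane potentials return to rest, synaptic activations, rate estimates
#' and eligibility traces to zero.  Weights are untouched.  Called at the
#' start of every trial (trials are treated as independent: the inter-trial
#' interval is much longer than any dynamic time constant).
#'
#' @param net a [flex_network()].
#' @return the network with fresh dynamic state.
#' @export
reset_state <- function(net) {
  net$state <- lapply(net$groups, function(g)
    list(v = rep(g$params$EL, g$n),
         s_fast = rep(0, g$n), s_slow = rep(0, g$n),
         r = rep(0, g$n), ref_until = rep(-1e18, g$n)))
  for (nm in names(net$projections)) {
    pj <- net$projections[[nm]]
    if (pj$rule != RULE_CODES[["fixed"]]) {
      net$projections[[nm]]$Tp[] <- 0
      net$projections[[nm]]$Td[] <- 0
    }
  }
  net
}

# events data.frame -> the numeric matrix the C++ loop consumes
compile_events <- function(net, events) {
  gn <- names(net$groups)
  if (is.null(events) || nrow(events) == 0)
    return(matrix(0, 0, 4))
  m <- matrix(0, nrow(events), 4)
  for (i in seq_len(nrow(events))) {
    id <- as.character(events$stimulus[i])
    if (id == "us") {
      m[i, 1] <- match("us", gn) - 1
      m[i, 4] <- net$config$us_amp * events$magnitude[i]
    } else {
      tgt <- paste0("cs_", id)
      if (!tgt %in% gn)
        stop("unknown stimulus id '", id, "': no column in the network")
      m[i, 1] <- match(tgt, gn) - 1
      m[i, 4] <- net$config$stim_amp * events$magnitude[i]
    }
    m[i, 2] <- events$onset[i]
    m[i, 3] <- events$duration[i]
  }
  m
}

# low-level trial driver shared by run_trial / step_network
sim_call <- function(net, events_mat, n_steps, n_warm, learning,
                     record_every, bin_width, bin_groups) {
  gn <- names(net$groups)
  stride <- max(1L, as.integer(round(record_every / net$dt)))
  bg <- match(bin_groups, gn) - 1L
  if (anyNA(bg)) stop("unknown group in bin_groups")
  proj_c <- lapply(unname(net$projections), function(p) {
    p$src <- match(p$src, gn) - 1L
    p$tgt <- match(p$tgt, gn) - 1L
    p$rule <- as.integer(p$rule)
    p
  })
  res <- cpp_run_network(
    state = unname(net$state[gn]),
    group_params = lapply(unname(net$groups[gn]), function(g)
      list(par = par_vector(g$params),
           tonic_extra = g$tonic_extra %||% NULL)),
    projections = proj_c,
    events = events_mat, dt = net$dt, n_steps = as.integer(n_steps),
    n_warm = as.integer(n_warm), learning = learning,
    r0 = net$r0, theta = net$theta, da_index = match("da", gn) - 1L,
    record_stride = stride, bin_width = bin_width,
    bin_groups = bg)
  # fold updated state and weights back into the network object
  st <- res$state
  for (i in seq_along(gn)) {
    s <- st[[i]]
    net$state[[gn[i]]] <- list(v = as.double(s$v),
                               s_fast = as.double(s$s_fast),
                               s_slow = as.double(s$s_slow),
                               r = as.double(s$r),
                               ref_until = as.double(s$ref_until))
  }
  pn <- names(net$projections)
  for (i in seq_along(pn)) {
    upd <- res$projections[[i]]
    net$projections[[pn[i]]]$W <- upd$W
    if (!is.null(upd$Tp)) {
      net$projections[[pn[i]]]$Tp <- upd$Tp
      net$projections[[pn[i]]]$Td <- upd$Td
    }
  }
  plastic_names <- pn[vapply(net$projections, function(p)
    p$rule != RULE_CODES[["fixed"]], logical(1))]
  colnames(res$pop_rates) <- gn
  if (ncol(res$trace_p)) {
    colnames(res$trace_p) <- plastic_names
    colnames(res$trace_d) <- plastic_names
  }
  names(res$counts) <- bin_groups
  list(net = net, res = res)
}

#' Simulate one trial
#'
#' Resets the dynamic state (weights persist), runs an unrecorded warm-up so
#' rate filters settle, then simulates the trial with the given event
#' schedule.  One synchronous update per step: conductances, membranes,
#' spikes, activations, rates, reinforcement, then trace and weight updates
#' on the plastic projections (when `learning`).
#'
#' @param net a [flex_network()].
#' @param events data.frame with columns `stimulus` (id, or `"us"` for
#'   reward), `onset`, `duration` (ms) and `magnitude`; or a
#'   one-trial schedule from the protocol constructors.
#' @param trial_length trial duration (ms).
#' @param learning enable plasticity for this trial.
#' @param record_every sampling interval of the recorded traces (ms).
#' @param bin_width spike-count bin width (ms) for the binned recordings.
#' @param bin_groups groups whose per-neuron binned spike counts are kept.
#' @param reset reset dynamic state before the trial (default) or continue
#'   from the current state.
#' @return list with `recording` (class `flex_trial`: `time`, `pop_rates`,
#'   `D`, mean eligibility traces, binned `counts`) and the updated `net`.
#' @export
run_trial <- function(net, events, trial_length = 1600, learning = TRUE,
                      record_every = 1, bin_width = 50,
                      bin_groups = c("da", "gaba"), reset = TRUE) {
  stopifnot(inherits(net, "flex_network"))
  if (inherits(events, "event_schedule")) {
    trial_length <- events$trial_length
    learning <- learning && events$learning
    events <- events$events
  }
  if (!is.null(events) && nrow(events) > 0 &&
      any(events$onset + events$duration > trial_length))
    stop("event extends beyond trial_length")
  if (reset) net <- reset_state(net)
  n_steps <- as.integer(round(trial_length / net$dt))
  n_warm <- as.integer(round(net$config$warm_ms / net$dt))
  out <- sim_call(net, compile_events(net, events), n_steps, n_warm,
                  learning, record_every, bin_width, bin_groups)
  rec <- structure(list(
    time = as.double(out$res$time),
    pop_rates = out$res$pop_rates,
    D = as.double(out$res$D),
    trace_p = out$res$trace_p, trace_d = out$res$trace_d,
    counts = out$res$counts,
    events = events, dt = net$dt, record_every = record_every,
    bin_width = bin_width, r0 = net$r0, theta = net$theta
  ), class = "flex_trial")
  list(recording = rec, net = out$net)
}

#' Advance the network by a few synchronous steps
#'
#' Low-level stepper over the current dynamic state (no reset, no warm-up);
#' mainly useful for inspecting the update order and for tests.  Drive is a
#' named vector of stimulus magnitudes held constant over the window.
#'
#' @param net a [flex_network()].
#' @param drive named numeric vector (`c(cue = 1)`, `"us"` for reward), or
#'   `NULL` for no input.
#' @param n_steps number of steps of length `net$dt`.
#' @param learning enable plasticity.
#' @return list with `recording` and updated `net`, as [run_trial()].
#' @export
step_network <- function(net, drive = NULL, n_steps = 1, learning = FALSE) {
  stopifnot(inherits(net, "flex_network"))
  span <- n_steps * net$dt
  events <- if (length(drive))
    data.frame(stimulus = names(drive), onset = 0, duration = span,
               magnitude = as.double(drive))
  else NULL
  out <- sim_call(net, compile_events(net, events), n_steps, 0L, learning,
                  record_every = net$dt, bin_width = span,
                  bin_groups = character(0))
  rec <- structure(list(time = as.double(out$res$time),
                        pop_rates = out$res$pop_rates,
                        D = as.double(out$res$D),
                        r0 = net$r0, theta = net$theta,
                        dt = net$dt, record_every = net$dt),
                   class = "flex_trial")
  list(recording = rec, net = out$net)
}

#' Mean weights of the plastic pathways
#'
#' @param object a `flex_network`.
#' @param ... unused.
#' @return named numeric vector of mean synaptic weights (nS) for each
#'   plastic projection.
#' @export
coef.flex_network <- function(object, ...) {
  pl <- Filter(function(p) p$rule != RULE_CODES[["fixed"]],
               object$projections)
  vapply(pl, function(p) mean(p$W), numeric(1))
}

#' @export
print.flex_network <- function(x, ...) {
  cat("<flex_network> ", length(x$spec$stimuli), " column(s): ",
      paste(x$spec$stimuli, collapse = ", "), "\n", sep = "")
  cat("  populations: ", paste0(names(x$groups), "(",
      vapply(x$groups, function(g) g$n, integer(1)), ")",
      collapse = " "), "\n", sep = "")
  cat("  plastic pathways:\n")
  w <- coef(x)
  for (nm in names(w))
    cat(sprintf("    %-8s mean weight %.4f nS\n", nm, w[nm]))
  invisible(x)
}

#' @export
summary.flex_network <- function(object, ...) {
  cat("Model with", length(object$spec$stimuli), "cue column(s) and a",
      "shared reward module\n")
  cat("dt =", object$dt, "ms; DA baseline r0 =", object$r0,
      "Hz; neutral half-width theta =", object$theta, "Hz\n")
  print(coef(object))
  invisible(object)
}

#' Duration of the Timer population response
#'
#' Time from cue onset until the Timer population rate of the given column
#' last falls below half of its peak (plateau) value.  Returns `NA` (absent,
#' distinguishable from zero) when the Timer never becomes active.
#'
#' @param recording a `flex_trial` from [run_trial()].
#' @param column stimulus id of the column.
#' @param cs_onset cue onset (ms); defaults to the column's event onset in
#'   the recording.
#' @param min_rate activity floor (Hz) below which the Timer counts as
#'   silent.
#' @return duration in ms, or `NA_real_`.
#' @export
timer_duration <- function(recording, column, cs_onset = NULL,
                           min_rate = 5) {
  stopifnot(inherits(recording, "flex_trial"))
  gcol <- paste0("timer_", column)
  if (!gcol %in% colnames(recording$pop_rates))
    stop("no Timer population for column '", column, "'")
  if (is.null(cs_onset)) {
    ev <- recording$events
    hit <- which(as.character(ev$stimulus) == column)
    if (!length(hit)) stop("cs_onset not given and no cue event found")
    cs_onset <- min(ev$onset[hit])
  }
  rate <- recording$pop_rates[, gcol]
  t <- recording$time
  post <- t >= cs_onset
  if (max(rate[post]) < min_rate) return(NA_real_)
  # plateau = median rate over the active period, so the cue-driven
  # transient peak does not distort the half-height criterion
  plateau <- median(rate[post & rate >= min_rate])
  above <- post & rate >= plateau / 2
  max(t[above]) - cs_onset
}

#' Time of a population's peak rate
#'
#' @param recording a `flex_trial`.
#' @param group population name (e.g. `"msg_cs1"`, `"da"`).
#' @return time (ms) of the maximum of the population rate trace.
#' @export
population_peak_time <- function(recording, group) {
  stopifnot(inherits(recording, "flex_trial"))
  if (!group %in% colnames(recording$pop_rates))
    stop("unknown group '", group, "'")
  recording$time[which.max(recording$pop_rates[, group])]
}

#' @export
print.flex_trial <- function(x, ...) {
  cat("<flex_trial> ", length(x$time), " samples (",
      x$record_every, " ms), groups: ",
      paste(colnames(x$pop_rates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.flex_trial <- function(x, groups = colnames(x$pop_rates), ...) {
  graphics::matplot(x$time, x$pop_rates[, groups, drop = FALSE],
                    type = "l", lty = 1, xlab = "time (ms)",
                    ylab = "population rate (Hz)", ...)
  graphics::legend("topright", legend = groups, col = seq_along(groups),
                   lty = 1, cex = 0.7)
  invisible(x)
}
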