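# Experiment configuration (JSON/YAML), validation with field paths, and
# the reproduction driver that regenerates each simulation figure's data
# from one call.

config_template <- function() {
  list(
    network = list(stimuli = "cs1", n = 100, n_vta = 100),
    model = flex_defaults(),
    protocol = list(name = "trace", n_trials = 40, cs_onset = 100,
                    cs2_onset = 800, us_onset = 1100, magnitude = 1,
                    trial_length = 1600),
    analysis = list(bin_width = 50, n_auroc_trials = 25,
                    response_window = 250),
    seed = 1,
    out_dir = "."
  )
}

check_keys <- function(value, template, path = "") {
  if (!is.list(template) || !is.list(value)) return(invisible())
  unknown <- setdiff(names(value), names(template))
  if (length(unknown))
    stop("unknown config key: ", paste0(sub("^\\.", "", path), ".",
                                        unknown[1]), call. = FALSE)
  for (nm in names(value))
    check_keys(value[[nm]], template[[nm]], paste0(path, ".", nm))
  invisible()
}

validate_config <- function(cfg) {
  num_fields <- list(
    c("network", "n"), c("network", "n_vta"),
    c("model", "dt"), c("model", "r0"), c("model", "theta"),
    c("protocol", "n_trials"), c("protocol", "trial_length"))
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config field ", paste(f, collapse = "."),
           " must be a single positive number", call. = FALSE)
  }
  for (nm in c("eta_p", "eta_d", "tau_p", "tau_d", "tmax_p", "tmax_d")) {
    for (pj in c("tt", "cd")) {
      v <- cfg$model$conn[[pj]]$trace[[nm]]
      if (!is.null(v) && (!is.numeric(v) || v <= 0))
        stop("config field model.conn.", pj, ".trace.", nm,
             " must be positive", call. = FALSE)
    }
  }
  cfg
}

#' Load and validate an experiment configuration
#'
#' Reads a JSON or YAML configuration, rejects unknown keys (reporting the
#' offending field path), fills all documented defaults and validates basic
#' invariants.
#'
#' @param path file path (`.json`, `.yaml` or `.yml`).
#' @return object of class `experiment_config`: the fully resolved
#'   configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$model$conn <- lapply(raw$model$conn, function(cn) {
    if (!is.null(cn$trace)) cn$trace <- do.call(trace_params, cn$trace)
    cn
  })
  tpl <- config_template()
  check_keys(raw, tpl)
  cfg <- modifyList(tpl, raw)
  cfg <- validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

#' Write a configuration to JSON or YAML
#'
#' @param cfg configuration list (e.g. from [load_config()]).
#' @param path destination path; format chosen by extension.
#' @return the path, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$model$conn <- lapply(cfg$model$conn, function(cn) {
    if (!is.null(cn$trace)) cn$trace <- unclass(cn$trace)
    cn
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path)
  else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

write_trial_csv <- function(rec, file) {
  df <- data.frame(time_ms = rec$time, rec$pop_rates, D = rec$D,
                   check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
}

#' Regenerate a simulation figure's data
#'
#' Runs the corresponding protocol and analysis end to end and writes
#' plotting-ready CSVs plus a JSON manifest (configuration echo, seed,
#' package version) into `out_dir`.  Deterministic per seed.
#'
#' * `rnn_history`: the fixed-RNN demonstration - trajectories for the
#'   A-B-C and B-A-C sequences, shared-frame principal-component
#'   projections, and the post-cue divergence curve.
#' * `trace`: single-cue trace conditioning - per-trial reinforcement
#'   integrals and mean weights, plus rate traces for the first, middle
#'   and final trials.
#' * `integrated_rpe`: the per-trial integrated-reinforcement comparison -
#'   spiking-model integrals (with a reward-only baseline block) alongside
#'   TD(lambda) totals for discount factors 1, 0.99 and 0.95.
#' * `sequential`: two-cue sequential conditioning with per-trial stage
#'   labels.
#'
#' @param figure one of `"rnn_history"`, `"trace"`, `"integrated_rpe"`,
#'   `"sequential"`.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param n_trials optional trial-count override for the session.
#' @return invisible list of the objects written.
#' @export
reproduce <- function(figure = c("trace", "sequential", "integrated_rpe",
                                 "rnn_history"),
                      seed = 1, out_dir = "reproduce_out",
                      n_trials = NULL) {
  figure <- match.arg(figure)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed)
  out <- list()

  if (figure == "rnn_history") {
    rnn <- fixed_rnn(K = 500, g = 1.5, tau = 50, seed = seeds[["rnn"]])
    seq_abc <- data.frame(stimulus = c("A", "B", "C"),
                          onset = c(0, 500, 1000))
    seq_bac <- data.frame(stimulus = c("B", "A", "C"),
                          onset = c(0, 500, 1000))
    ta <- simulate_rnn(rnn, seq_abc, duration = 2000)
    tb <- simulate_rnn(rnn, seq_bac, duration = 2000)
    pr <- project_pca(list(abc = ta, bac = tb))
    dv <- trajectory_divergence(ta, tb, align_at = 1000)
    write.csv(data.frame(time_ms = attr(ta, "time"),
                         abc_pc = pr$projections[[1]],
                         bac_pc = pr$projections[[2]]),
              file.path(out_dir, "rnn_projections.csv"), row.names = FALSE)
    write.csv(data.frame(time_ms = dv$time, distance = dv$distance),
              file.path(out_dir, "rnn_divergence.csv"), row.names = FALSE)
    out <- list(divergence = dv$summary, explained = pr$explained)
  }

  if (figure == "trace") {
    net <- flex_network("cs1", seed = seeds[["build"]])
    sess <- trace_conditioning(n_trials = n_trials %||% 40)
    hist <- run_session(net, sess, seed = seeds[["sim"]])
    ints <- session_integrals(hist)
    write.csv(data.frame(trial = seq_along(ints), integrated_D = ints),
              file.path(out_dir, "trace_integrals.csv"), row.names = FALSE)
    write.csv(hist$weights, file.path(out_dir, "trace_weights.csv"),
              row.names = FALSE)
    picks <- unique(c(1, ceiling(length(hist$trials) / 8),
                      length(hist$trials)))
    for (i in picks)
      write_trial_csv(hist$trials[[i]],
                      file.path(out_dir, sprintf("trace_trial_%02d.csv", i)))
    out <- list(history = hist)
  }

  if (figure == "integrated_rpe") {
    net <- flex_network("cs1", seed = seeds[["build"]],
                        config = list(conn = list(
                          tt = list(eta = flex_defaults()$conn$tt$eta / 2),
                          cd = list(eta = flex_defaults()$conn$cd$eta / 2))))
    base <- us_only_session(n_trials = n_trials %||% 100)
    train <- trace_conditioning(n_trials = n_trials %||% 60)
    hist <- run_session(net, c(base, train), seed = seeds[["sim"]])
    flex_int <- session_integrals(hist)
    n_bins <- 32
    td_tot <- sapply(c(1, 0.99, 0.95), function(g) {
      m <- td_model(n_bins, gamma = g, lambda = 0.9, alpha = 0.1)
      integrated_rpe(run_td_session(m, n_trials = length(flex_int),
                                    cs_bin = 3, us_bin = 23,
                                    n_bins = n_bins)$rpe)
    })
    df <- data.frame(trial = seq_along(flex_int), flex = flex_int,
                     td_gamma_1 = td_tot[, 1], td_gamma_099 = td_tot[, 2],
                     td_gamma_095 = td_tot[, 3])
    write.csv(df, file.path(out_dir, "integrated_rpe.csv"),
              row.names = FALSE)
    out <- list(table = df)
  }

  if (figure == "sequential") {
    net <- flex_network(c("cs1", "cs2"), seed = seeds[["build"]])
    sess <- sequential_conditioning(n_trials = n_trials %||% 70)
    hist <- run_session(net, sess, seed = seeds[["sim"]])
    stages <- stage_classifier(hist)
    write.csv(data.frame(trial = seq_along(stages), stage = stages,
                         attr(stages, "responses")),
              file.path(out_dir, "sequential_stages.csv"),
              row.names = FALSE)
    write.csv(hist$weights, file.path(out_dir, "sequential_weights.csv"),
              row.names = FALSE)
    out <- list(history = hist, stages = stages)
  }

  manifest <- list(figure = figure, seed = seed,
                   derived_seeds = as.list(derive_seeds(seed)),
                   package_version = as.character(
                     utils::packageVersion("flexdop")),
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
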