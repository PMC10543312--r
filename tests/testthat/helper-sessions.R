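# Memoized heavy simulations shared across acceptance tests.  Seeds are
# fixed so every run of the suite exercises the same realization of the
# study conditions.

.session_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .session_cache))
    assign(key, force(expr), envir = .session_cache)
  get(key, envir = .session_cache)
}

# full single-cue trace-conditioning study: 40 training trials plus 10
# learning-off probe trials at the trained weights
trained_trace <- function() memo("trace", {
  net <- flex_network("cs1", seed = 1)
  hist <- run_session(net, trace_conditioning(n_trials = 40), seed = 2,
                      record_every = 2)
  probes <- run_session(hist$net, trace_conditioning(n_trials = 10),
                        seed = 3, learning = FALSE, record_every = 2)
  list(hist = hist, probes = probes)
})

# two-cue sequential-conditioning study
trained_sequential <- function() memo("sequential", {
  net <- flex_network(c("cs1", "cs2"), seed = 1)
  hist <- run_session(net, sequential_conditioning(n_trials = 70),
                      seed = 2, record_every = 2)
  probes <- run_session(hist$net, sequential_conditioning(n_trials = 6),
                        seed = 3, learning = FALSE, record_every = 2)
  list(hist = hist, probes = probes)
})

trace_responses <- function(hist) {
  t(vapply(hist$trials, response_magnitudes, numeric(2),
           windows = list(CS = c(100, 350), US = c(1100, 1350))))
}
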