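Package: flexdop
Title: Spiking-Network Model of Flexibly Learned Dopaminergic Reward Timing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a biophysical spiking-network account of how midbrain
    dopamine neurons come to signal reward timing.  Feature-specific cortical
    microcircuits of Timer, Inhibitory and Messenger populations learn, via a
    dopamine-gated two-eligibility-trace plasticity rule, temporal basis
    functions that span the cue-reward delay, while plastic cue-to-dopamine
    and Messenger-to-GABA pathways transfer and suppress phasic dopamine
    responses.  Includes conditioning protocols (trace, sequential, omission,
    extinction, blocking and unblocking), reference temporal-difference
    learners over fixed temporal bases, a fixed random recurrent network
    demonstration, and spike-count auROC analysis utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
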