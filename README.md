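# flexdop

A spiking-network model of how midbrain dopamine neurons learn to signal
reward timing — with the temporal basis itself *learned*, not assumed.

## The problem and the model

Classic accounts of conditioning map phasic dopamine onto the reward
prediction error (RPE) of temporal-difference (TD) learning, computed over
a *fixed* temporal basis: every cue is assumed to come pre-equipped with a
chain of "microstates" tiling all possible cue–reward delays.  `flexdop`
implements the alternative in which feature-specific cortical microcircuits
*learn* their temporal basis during conditioning:

* **Timers** — per-cue populations whose recurrent weights are learned so
  that their persistent firing spans the cue–reward delay;
* **Messengers** — cells that fire at the end of the Timer envelope, i.e.
  at the expected reward time;
* a **reward module** of dopaminergic (DA) and GABAergic neurons at a
  ~5 Hz baseline, where reinforcement is the thresholded departure of the
  DA population rate from baseline:

  D(t) = r_DA − (r₀+θ) above the neutral band [r₀−θ, r₀+θ], r_DA − (r₀−θ)
  below it, and 0 inside.

All neurons are conductance-based leaky integrate-and-fire units.  Three
pathways are plastic under dopamine-gated rules: the Timer recurrence and
the cue→DA pathway use the competitive two-eligibility-trace rule

  τₐ dTᵃ/dt = −Tᵃ + ηₐ H (Tᵃmax − Tᵃ),  a ∈ {p, d};  dW/dt = η D (Tᵖ − Tᵈ),

where H is the Hebbian product of pre/post rate estimates (divisively
suppressed in cortex during large positive D — event boundaries); the
Messenger→GABA pathway uses the dopamine-modulated Hebbian rule
dW/dt = η D rᵢ rⱼ, whose fixed point is reached when the reward-locked
dopamine it suppresses hits zero.  The package also ships reference
TD(0)/TD(λ) learners over a complete-serial-compound basis, a fixed random
recurrent network demonstrating why a frozen reservoir cannot serve as a
universal temporal basis, and spike-count auROC analysis tools.

## Worked example

```r
library(flexdop)

net <- flex_network("cs1", seed = 1)
net
#> <flex_network> 1 column(s): cs1
#>   populations: cs_cs1(100) timer_cs1(100) inh_cs1(100) msg_cs1(100)
#>                us(100) da(100) gaba(100)
#>   plastic pathways:
#>     tt_cs1   mean weight 0.0450 nS
#>     cd_cs1   mean weight 0.0002 nS
#>     mg_cs1   mean weight 0.0000 nS

# 40 trials of trace conditioning: cue at 100 ms, reward at 1100 ms
hist <- run_session(net, trace_conditioning(n_trials = 40), seed = 2)

ints <- session_integrals(hist)
round(c(trial_1 = ints[1], max_later = max(ints[-1])))
#> trial_1 max_later
#>    1967      5050
```

The per-trial integral of the reinforcement D(t) rises mid-training to
about 2.6× the naive-reward trial — the signature that distinguishes this
model from any TD learner, whose per-trial summed RPE can never exceed the
first unexpected reward (compare `integrated_rpe(run_td_session(...)$rpe)`,
which is exactly conserved for γ = 1 and shrinks for γ < 1).

Probing the trained network with learning off:

```r
probe <- run_session(hist$net, trace_conditioning(n_trials = 6),
                     seed = 3, learning = FALSE)
mean(sapply(probe$trials, population_peak_time, group = "msg_cs1"))
#> 909     # Messenger population peak (ms); learned, started near 450
mean(sapply(probe$trials, timer_duration, column = "cs1", cs_onset = 100))
#> 768.2   # Timer persistent-activity duration (ms); started near 330
```

The Timer has learned to span most of the 1000 ms delay and the Messenger
peak has moved toward the reward time (across independent realizations the
learned equilibrium sits 10–20% short of the programmed delay; the methods
vignette explains why).  Withholding
the reward after training produces the characteristic dopamine dip —
`run_session(hist$net, omission_extinction(trace_conditioning(), mode =
"single_omission"), learning = FALSE)` drops the DA population to ~0.9 Hz
at the expected reward time, far below the 4 Hz lower reinforcement
threshold — and a 40-trial extinction block returns the cue response to
~11% of its converged value.  Blocking and unblocking:
`blocking_unblocking(reward_boost = 1)` leaves a subsequently probed
inserted cue at baseline (−2 Hz), while `reward_boost = 2` recruits it
strongly (+40 Hz).

See `vignettes/model-methods.Rmd` for the model's assumptions, parameter
choices, numerical decisions and known limitations.

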