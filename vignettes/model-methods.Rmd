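---
title: "A spiking-network model of learned dopaminergic reward timing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-network model of learned dopaminergic reward timing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Midbrain dopamine neurons respond to unexpected rewards and, after
conditioning, to the cues that predict them.  The textbook account maps this
onto temporal-difference (TD) learning, in which dopamine firing reports a
reward prediction error (RPE) computed over a *fixed* temporal basis: every
cue is assumed to trigger its own pre-existing chain of microstates that
tiles all possible cue-reward delays.  `flexdop` implements an alternative in
which the temporal basis itself is *learned*: feature-specific cortical
microcircuits acquire, through dopamine-gated plasticity, persistent-activity
"Timers" that span the cue-reward delay, and "Messenger" cells that fire at
the expected reward time.  Dopamine here is an instructive signal for
building temporal models, not a strict RPE — a distinction with testable
consequences (notably, the per-trial integral of the dopamine reinforcement
can transiently *exceed* the response to the first unexpected reward, which
no TD variant allows).

The package contains the full spiking implementation, the conditioning
protocols (trace, sequential, omission, extinction, blocking/unblocking),
reference TD(0)/TD(λ) learners over fixed bases, a fixed random recurrent
network used to show why a universal frozen reservoir cannot serve as a
temporal basis, and the spike-count auROC analyses used to summarize the
simulated data.

## Network dynamics

All neurons are conductance-based leaky integrate-and-fire units,

$$C\,\dot v_i = g_L(E_L - v_i) + g_{E,i}(E_E - v_i) + g_{I,i}(E_I - v_i)
  + I_{\text{tonic}} + \sigma\xi_i(t),$$

with a spike and reset at threshold and an absolute refractory period during
which the membrane is clamped at the reset potential.  Each neuron carries a
saturating synaptic activation per channel,

$$\dot s_i = -s_i/\tau_s + \rho(1 - s_i)\textstyle\sum_k \delta(t - t_i^k),$$

on two channels: a fast one (τ = 5 ms, AMPA-like) and a slow one
(τ = 100 ms, NMDA-like).  A projection reads one channel of its source
population; conductances are `g = W s` with non-negative weights, the sign
carried by the excitatory/inhibitory channel.  Each neuron also carries an
online rate estimate, the unit-area exponential filter of its spikes
(τ_r = 50 ms), which is what the plasticity rules see.

Membrane constants are standard cortical LIF values (τ_m = 20 ms,
E_L = −70 mV, E_E = 0 mV, E_I = −80 mV, v_th = −50 mV, v_reset = E_L,
t_ref = 2 ms); none are printed in the source material, and none are
critical.  The noise term is white current noise whose per-step voltage
increment has standard deviation σ√dt/C, making trajectories statistically
invariant to the step size.

Integration is forward Euler.  The package default is dt = 0.5 ms: the
fastest time constant in the model is 5 ms, the unit tests verify first-order
convergence of the membrane trajectories against the closed-form
subthreshold solution, and at 0.5 ms a full 40-trial conditioning session
runs in about a minute.  dt is a configuration field; nothing in the code
assumes a particular value.

## Architecture

One cortical "column" per stimulus, plus a shared reward module:

* `cs_<id>` — a relay population driven by the external cue conductance
  pulse (150 ms by default; onsets come from the protocol).
* `timer_<id>` — Timers, recurrently connected through the slow channel.
* `inh_<id>` — inhibitory cells driven by Timers (fast channel).
* `msg_<id>` — Messengers, receiving slow Timer excitation and fast
  inhibition from `inh`.
* `us` — a relay for intrinsically rewarding input, with fixed sparse
  excitatory projections onto `da`.
* `da`, `gaba` — the reward module: 100 dopaminergic and 100 GABAergic
  neurons with tonic noisy drive calibrated to a ~5 Hz baseline.  `gaba`
  inhibits `da` through the slow channel (GABA-B-like kinetics): the
  ~100 ms lag places the *learned* reward-locked inhibition, which follows
  the Messenger burst, onto the reward itself rather than slightly before
  it, where its dopamine dip would otherwise repel the Timer from full
  alignment.

Three pathways are plastic: the Timer recurrence (two-trace rule, cortical
variant), cue relay → `da` (two-trace rule, reward-module variant), and
Messenger → `gaba` (dopamine-modulated Hebbian rule).  Everything else is
fixed, with log-normal weight heterogeneity and, where declared, Bernoulli
sparsity (15% for the cue→DA and US→DA projections, which is what produces
the diversity of single-unit responses in the auROC maps).

### How the Messenger window works

Messengers must fire at the *end* of the Timer envelope.  During Timer
activity the inhibitory cells, driven through the fast channel, keep the
Messengers suppressed; the Messengers' excitation arrives through the slow
channel.  When Timer activity collapses, the fast inhibition disappears
within tens of milliseconds while the slow excitation persists for a few
hundred, opening a transient window in which the Messengers burst.  The
inhibitory population is given a small tonic depolarization (60 pA) so that
it keeps tracking Timer activity down to low rates — this sets how deep into
the Timer decay the Messenger burst is released, and thereby the ~100-150 ms lag
between the Timer's half-height offset and the Messenger peak.

### Timer timing without fragile attractor tuning

A homogeneous population with saturating slow recurrence is effectively
bistable: it either dies with the stimulus or persists indefinitely, and
graded durations exist only in a razor-thin weight band near the bifurcation
where the lifetime is dominated by noise.  The Timers here instead carry an
evenly spaced ladder of intrinsic excitabilities (tonic offsets ±200 pA
across the population; spaced, not sampled, so the duration-weight map does
not depend on a particular random draw).  As the slow recurrent drive decays, the least excitable
neurons drop out first, weakening the drive further; the population sheds
members progressively and collapses at a time set by the recurrent weight.
This makes duration a smooth, mostly deterministic function of the weight
over the whole 250–1500 ms range (trial-to-trial s.d. ≈ 5% of the duration),
which is also what lets the learning rule servo the duration reliably.

Because Hebbian per-synapse learning on the recurrent pathway would
concentrate weight inside the most excitable subgroup (destroying the graded
shed and locking the population on), the recurrence is learned as a single
population-level weight scale: one scalar pair of eligibility traces driven
by the population-mean rate product, applied as a uniform shift of the
whole matrix.  Per-synapse heterogeneity from initialization is preserved.

## Plasticity

The reinforcement signal is computed from the dopamine population mean rate
r_DA(t) as a piecewise-linear function that is zero inside a neutral band
r_0 ± θ (defaults 5 ± 1 Hz) and equals the linear excess outside it.  D(t)
is global (dopamine is a volume transmitter) and signed: firing above the
band reinforces, below it punishes.

Each plastic synapse (or the population, for the scalar variant) carries two
saturating eligibility traces driven by the Hebbian product H of pre- and
postsynaptic rate estimates:

$$\tau_a\dot T^a = -T^a + \eta_a H (T^a_{\max} - T^a), \qquad a \in \{p, d\},$$

and the weight update is the reinforcement-weighted competition
$\dot W = \eta\, D(t)\,(T^p - T^d)$, clipped to [0, W_max].  In the cortical
module the Hebbian product is divisively suppressed during large positive
reinforcement, $H \to H/(1+\alpha D)$ for $D>0$: large positive dopamine
transients act as event boundaries that stop cortical traces from binding
across them.

### Trace ordering and why the fixed point is attractive

The defaults make the LTD trace dominant during and just after Hebbian
activation (T^d_max = 1.3 T^p_max with equal activation constants, so the LTD
trace both rises and decays faster: τ_d = 200 ms versus τ_p = 1200 ms),
and the LTP trace dominant at long delays.  The two traces therefore cross
once, a short lag c ≈ 40–80 ms after activation ends.  For the Timer
recurrence this makes the trial fixed point
$\int D(t)\,(T^p-T^d)\,dt = 0$ attractive: while the Timer is too short,
reward arrives well after the crossing, T^p > T^d, and positive D
potentiates (the Timer grows); if the Timer overshoots so that reward falls
inside the activation envelope, T^d > T^p and the same positive D
depresses.  The opposite ordering (LTP dominant early, LTD at long delays)
makes that fixed point repulsive — a too-short Timer would be pushed
shorter — which is why the package uses this configuration.

For the cue→DA pathway the LTP activation constant is larger
(η_p = 0.0075 versus η_d = 0.002), so during the brief cue bump the two
traces rise at comparable rates and the pathway's *own* dopamine response
produces only a weak net self-term.  The cue response therefore grows while
reward-evoked dopamine persists, and settles at a moderate amplitude rather
than either collapsing (LTD-dominant self-term) or running away
(LTP-dominant).  This parameter sits between two regimes a few tens of
percent away on either side, and is the main knob controlling the
steady-state cue response.

The Messenger→GABA pathway uses the plain dopamine-modulated Hebbian rule
$\dot W = \eta D\, r_i r_j$.  Its fixed point is self-imposed: the pathway
potentiates whenever Messenger/GABA coactivity meets positive D, which is
exactly the configuration it removes (by driving GABA to cancel the
reward-locked dopamine), and mistimed growth is unlearned by the negative D
its own misplaced inhibition produces.  Its rate constant is deliberately
the slowest in the model: reward-locked suppression must not complete
before the Timers have grown to span the delay, or learning freezes early
(the same ordering requirement stated for the model's fixed points).

All trace and rate parameters are exposed in `flex_defaults()`; none are
printed in the source material.  They were calibrated once, on the
single-cue trace-conditioning protocol, to reproduce the qualitative
learning dynamics (timer growth to the delay within 40 trials, cue response
emerging before reward-response suppression, messenger alignment with the
reward time), and are not adjusted per protocol.

## Protocols and study conditions

Trials are simulated independently: dynamic state and eligibility traces
reset at each trial start (the inter-trial interval is treated as much
longer than every dynamic time constant), weights persist.  Each trial
begins with a 300 ms unrecorded warm-up so rate filters settle at baseline.

* Trace conditioning: 40 trials, cue at 100 ms, reward at 1100 ms, 1600 ms
  trials.
* Sequential conditioning: cue 1 at 100 ms, cue 2 at 800 ms, reward at
  1500 ms, 2000 ms trials.  The default session length is 70 trials; the
  full four-stage progression is slower than single-cue learning because
  the reward-locked suppression must complete before the serial transfer
  can begin.
* Omission / extinction: cue-only trials appended to a trained session
  (one probe, or a block).
* Blocking / unblocking: phase 1 single-cue conditioning; phase 2 inserts a
  second cue at 600 ms with the reward unchanged at 1100 ms and magnitude
  multiplied by 1 (blocking) or >1 (unblocking).  Reward magnitude maps
  linearly onto the reward input conductance.
* Reward-only baseline block: 100 trials with plasticity off, used as the
  pre-learning reference for integrated-reinforcement comparisons.

## Reference models

The TD learners use a complete-serial-compound one-hot basis over 50 ms
bins (Gaussian microstimuli are available as an option), online TD(λ) with
accumulating traces, and per-trial eligibility reset.  With γ = 1 the
per-trial summed RPE telescopes exactly to the delivered reward — the
conservation against which the spiking model's transient excess is
contrasted.  λ defaults to 0.9, chosen to match the earlier modelling work
this comparison follows; with λ = 0 the learner reproduces the classic
backward-moving RPE bump, verified in the tests against a hand-iterated
tabular oracle.

The fixed-RNN demonstration integrates rate units
$\tau \dot u = -u + W\phi(u) + \text{input}(t)$ with φ = tanh, weights drawn
once from N(0, g²/K) (the gain-scaled 1/K-variance convention; the printed
form "N(0, gK)" is ambiguous and this is the standard reading), K = 500,
g = 1.5, τ = 50 ms.  Inputs are 100 ms steps along fixed random directions.
History dependence is quantified as the post-cue state distance between two
stimulus orders, normalized by the mean state norm, after aligning at the
shared cue.

## Analyses

* auROC per neuron and 50 ms bin between two conditions' spike-count
  distributions, computed by sweeping an integer criterion from zero to the
  maximum count, plotting P(active > c) against P(baseline > c), appending
  the (0,0)/(1,1) endpoints and integrating by trapezoid.  This equals
  P(active > baseline) + ½P(tie) and is verified in the tests against
  exhaustive pair counting.  The default is 25 trials per condition.
* Per-trial integrated reinforcement: the rectangle-rule integral of D(t)
  over the trial.
* Response magnitudes: mean dopamine population rate minus baseline in
  250 ms windows after each event onset.  Because the rate estimate is a
  causal 50 ms filter and the cue lasts 150 ms, event-locked responses peak
  100–150 ms after onset; window-mean magnitudes are insensitive to this
  lag.
* Timer duration: time from cue onset until the Timer population rate last
  falls below half of its plateau, where the plateau is the median rate
  over the active period (so the cue-driven transient peak does not distort
  the criterion).  A silent Timer is reported as `NA`, distinguishable
  from a zero duration.
* Stage labels for sequential conditioning from the sign pattern of the
  (cue 1, cue 2, reward) responses, thresholded at 25% of the trial-1
  reward response; ambiguous patterns are labeled `transitional` rather
  than forced into a stage.

## What the generator emulates, and what it does not

All inputs are synthetic: conductance pulses standing in for sensory cues
and rewards, stationary current noise standing in for background synaptic
bombardment.  The model makes no attempt at realistic sensory tuning,
behavioral readouts, probabilistic reward schedules, synapse-level release
stochasticity, or the emergence of the Timer/Messenger microcircuit from
unstructured connectivity (its fixed intra-column wiring is taken as given,
consistent with prior work showing such structure can self-organize).
Passing tests therefore show that the *mechanism* — learned temporal basis
plus dopamine-gated competition — produces the claimed dynamics under clean
conditions, not that it quantitatively fits any particular biological
dataset.

## Numerical choices and degenerate inputs

* Forward Euler, dt = 0.5 ms default; order-1 convergence is tested.
* Noise uses the R random stream throughout (including inside the compiled
  core), so every simulation is exactly reproducible given a seed;
  `derive_seeds()` expands one master seed into independent named streams.
* Non-finite membrane state aborts the simulation naming the neuron and
  step; empty sessions, mis-ordered event schedules, unknown stimulus ids
  and out-of-range events are rejected at construction.
* Weight clipping to [0, W_max] keeps conductances non-negative and bounds
  runaway; the Timer recurrence bound (9 nS population total) lies above
  the permanently-persistent regime, so it is the trace competition, not
  the clip, that normally stabilizes learning.
* auROC ties follow the strict criterion sweep; identical samples give 0.5
  exactly.

## Problem sizes

The shipped defaults are the study conditions: 100 neurons per population,
40-trial single-cue sessions, 70-trial sequential sessions, 10 s baseline
calibration runs, 25-trial auROC condition blocks.  The test suite runs
reduced populations (n = 40) for the plumbing tests and the full
conditions in the acceptance suite.

## Known limitations

* The learned timing equilibrates 10–15% short of the programmed delay:
  across independent builds the post-training Messenger peak sits near
  950–1030 ms for an 1100 ms reward (Timer half-height duration ~840 ms for
  a 1000 ms delay, with ~5–8% trial-to-trial jitter).  The cause is an
  equilibrium property, not noise: as the Messenger-driven inhibition
  becomes partially aligned it quenches the reinforcement that would push
  the Timer the rest of the way.
* For the same reason the reward-evoked dopamine response converges to
  roughly half of its initial amplitude rather than to baseline: the
  Messenger→GABA rule balances aligned potentiation against the unlearning
  produced by its own slightly mistimed dips.
* The steady-state cue response is sensitive to the cue-pathway LTP
  activation constant; values ~20% above the default produce a runaway cue
  response that in turn suppresses Timer growth.  This brittleness is a
  property of the self-referential cue→dopamine loop, not of the numerical
  scheme.
* In sequential conditioning the model shows the initialization and
  acquisition stages robustly, but the reward-depression and
  serial-transfer endpoints do not emerge under the shipped calibration:
  the first cue's Timer is reinforced through the later dopamine bumps all
  the way to the reward delay before the second cue's response is strong
  enough to act as an event boundary.  The dominant late dopamine response
  nevertheless sits at the first cue, as reported.
* Blocking and unblocking probe outcomes are bimodal over session
  realizations (roughly one run in four lands in the opposite mode),
  reflecting whether phase-1 reward suppression completed before phase 2.
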