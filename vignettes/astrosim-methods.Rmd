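---
title: "Neuron-astrocyte network simulation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuron-astrocyte network simulation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrosim)
```

# The cell model

Every cell in this package -- neuron or astrocyte -- obeys the two-variable
quadratic ("simple") spiking model

$$C\dot v = k(v - v_r)(v - v_t) - u + I, \qquad
  \dot u = a\,[\,b(v - v_r) - u\,],$$

with the hard event rule: when $v \ge v_{peak}$, set $v \leftarrow c$ and
$u \leftarrow u + d$. For neurons we use the classic cortical
regular-spiking parameter set ($C = 100$, $v_r = -60$, $v_t = -40$,
$k = 0.7$, $a = 0.03$, $b = -2$, $c = -50$, $d = 100$, $v_{peak} = 35$).

Astrocytes do not fire action potentials; their defining
electrophysiological signature is an approximately **linear** steady-state
current-voltage relation, in contrast with the N-shaped quadratic I-V curve
of neurons. Rather than introducing a separate formalism, the astrocyte is
expressed in the *same* equations with a parameter set chosen so that the
steady-state relation

$$I_{ss}(v) = (v - v_r)\,[\,b - k(v - v_t)\,]$$

is nearly linear over the physiological range: $C = 6$, $v_r = -70$,
$v_t = 1429.164$, $k = 2.77\times10^{-5}$, $b = -6.5\times10^{-4}$, with
the same reset constants as the neuron. Pushing $v_t$ far above the
operating range makes the quadratic term locally indistinguishable from a
line: `linearity_r2()` of the astrocyte curve over $v \in [-200, 30]$
exceeds 0.99, while the neuron curve is far from linear over the same
range. These astrocyte constants are scale-free labels, not physical
capacitances or voltages; the astrocyte's $v$ abstractly tracks
intracellular calcium. A threshold crossing in the astrocyte is interpreted
as a **glutamate release event**, not a spike.

Two consequences of this parameter set are worth knowing:

* Under the standard validation protocol (a constant $I = 4$ applied
  during steps 100-1000 of a 1000-step run) the astrocyte never reaches
  $v_{peak}$: `simulate_constant_current(astrocyte_params(), 4, ...)`
  reports zero events, and the membrane approaches but does not reach
  threshold.
* The equilibrium of $I_{ss}(v) = 4$ sits at $v \approx 35.4$, slightly
  *above* $v_{peak} = 35$, so a much longer injection at the same
  amplitude would eventually produce release events, and stronger currents
  do so quickly. The cell is only "silent" in the sense that matters: at
  physiological currents on physiological timescales. The
  simulation-versus-closed-form equilibrium checks in the test suite
  therefore use genuinely subthreshold currents ($I \in \{1,2,3\}$), where
  the two routes agree to much better than 0.5 voltage units.

## Parameter fitting

`fit_iv_params()` estimates cell parameters from a target I-V curve by
minimising the mean squared error between $I_{ss}(v)$ and the target
currents (Nelder-Mead). Only $k$, $b$ and $v_t$ shape the steady state:
$C$ and $a$ are timescales that cancel at equilibrium, and $c$, $d$,
$v_{peak}$ only govern the reset, so the default free set is
$\{k, b, v_t\}$ and $v_r$ is pinned to the target's zero-current voltage.
Because $b$ and $k \cdot v_t$ trade off along a near-flat valley of the MSE
surface, the meaningful output of the fit is the fitted *curve* (via
`predict()`/`fitted()`), not the raw parameter vector.

# Signalling pathways

All transmission -- synaptic neurotransmitter, astrocytic IP3, the
potassium pathway and glial glutamate -- is modelled as a superposition of
alpha-function kernels

$$f(t) = \frac{t}{\lambda}\, e^{(\lambda - t)/\lambda},$$

one kernel per release event, where $t$ is the time since the source cell
reached $v_{peak}$. The kernel rises from zero, peaks at exactly 1 at
$t = \lambda$, and decays; superposition is additive and unweighted, with
all gain applied by the network layer. Pathway time constants:
$\lambda = 125$ for synaptic lines, $\lambda = 100$ for the potassium
pathway, and $\lambda = 1000$ for the two slow astrocytic pathways (IP3
and glutamate). Kernels older than $10\lambda$ are dropped when a line is
evaluated; the neglected tail is below $1.3\times10^{-3}$ of the kernel
peak, which bounds the per-kernel error well under the integration
tolerances that matter anywhere downstream.

A note on units: the pathway constants and protocol lengths are treated as
**scale-free steps**, and only their ratios are meaningful (trials of 2000
steps, stimulation for 1000 steps, $\lambda \in \{100, 125, 1000\}$). No
attempt is made to map steps onto milliseconds.

# Network architectures

Both architectures share a feed-forward core: `n_pre = 10` presynaptic
neurons fully connected to `n_post = 2` postsynaptic neurons by 20 plastic
synapses. The **bipartite** network stops there. The **tripartite**
network adds one astrocyte per postsynaptic neuron. Astrocyte $j$:

* receives IP3 lines from *all* presynaptic neurons and a potassium line
  from its own postsynaptic neuron, each scaled by the fixed (non-plastic)
  weight $w_{fix} = 0.71$;
* on reaching threshold, emits glutamate into the cleft of each of its ten
  synapses (scaled by $w_{fix}$ and hence amplified by the plastic weight
  of that synapse on its way into the postsynaptic cell), plus a weak
  direct current into the postsynaptic membrane.

The cleft routing of glutamate is a deliberate design choice. Routing
glutamate *only* as a direct current scaled by $w_{fix}$ would give the
astrocyte a maximal influence of a few current units against synaptic
drive three orders of magnitude larger and a postsynaptic rheobase of
about 51 -- an astrocyte that cannot change a single spike. With cleft
routing, the astrocyte-side magnitudes are strikingly consistent: the
fixed-weighted IP3 + potassium drive reaches roughly 4-8 late in a trial,
exactly straddling the astrocyte's release threshold current
$I_{ss}(35) \approx 3.99$, so astrocytes activate when, and only when, the
presynaptic population has been persistently active.

Integration uses forward Euler with step $dt = 1$ and two substeps of
$dt/2$ for the voltage equation (a standard stability measure for this
model family; the recovery equation takes a single full step). Per step:
presynaptic neurons integrate their stimulus and feed the synaptic and IP3
lines; postsynaptic neurons integrate
$\sum_i w_{ij}\,[f_i(t) + w_{fix}\,g_j(t)] + w_{fix}\,g_j(t)$; astrocytes
integrate $w_{fix}\,[\sum_i \mathrm{IP3}_i(t) + K_j(t)]$. Gaussian voltage
noise of standard deviation `noise_sd` is added to every neuron (never an
astrocyte) at every step.

## The single-synapse demonstration

`simulate_single_synapse()` reduces the network to one presynaptic and one
postsynaptic neuron (plus one astrocyte in the tripartite case), drives
the presynaptic cell with a constant current of 70 for 1000 steps
(onset at step 100), and observes for 2500 steps. The run extends 1400
steps past stimulus offset because that is where the astrocyte's effect
lives: IP3 kernels ($\lambda = 1000$) keep *rising* after the presynaptic
neuron falls silent, the astrocyte crosses threshold, and its glutamate
sustains postsynaptic firing long after the bipartite synapse has decayed.
In matched runs the last bipartite postsynaptic event occurs a few hundred
steps after stimulus offset while tripartite activity continues to the end
of the observation window -- the architecture's signature effect. The
single-synapse weight is drawn from $[100, 400]$, the network default
scaled by the usual fan-in of ten, so one synapse carries the drive that
ten convergent synapses share in the full network.

# Reinforcement learning

Weights evolve by a three-factor, dopamine-gated rule. With $I_K$ the
integrated presynaptic line output of synapse $K$, $S_J$ the integral of
the positive part of postsynaptic voltage $J$ over the trial, and $D$ the
trial's dopamine level:

$$\Delta w = \alpha_w I_K [S_J - \theta_{NMDA}]^+ [D - D_{base}]^+ (w_{max} - w)
 - \beta_w I_K [S_J - \theta_{NMDA}]^+ [D_{base} - D]^+ w
 - \gamma_w I_K [\theta_{NMDA} - S_J]^+ [S_J - \theta_{AMPA}]^+ w,$$

clipped to $[0, w_{max}]$. At most one term is active for any
$(S_J, D)$: LTP for a strongly active postsynaptic cell with dopamine
above baseline, dopamine-dip LTD for a strongly active cell with dopamine
below baseline, and slow LTD for activation between the two receptor
thresholds; below $\theta_{AMPA}$ the weight is frozen.

Dopamine follows the reward-prediction error $\mathrm{RPE} = R - P$
through a piecewise-linear release function (1 above RPE = 1; 0 below
RPE = -0.25; $0.8\,\mathrm{RPE} + 0.2$ between), and the predicted reward
tracks obtained rewards with learning rate $\eta$:
$P \leftarrow P + \eta (R - P)$.

Defaults: $\alpha_w = 5\times10^{-10}$, $\beta_w = 2\times10^{-10}$,
$\gamma_w = 5\times10^{-13}$, $\theta_{NMDA} = 500$,
$\theta_{AMPA} = 150$, $w_{max} = 2000$, $\eta = 0.075$,
$D_{base} = 0.2$. Three of these deserve comment:

* The two activation thresholds are exposed as configurable because their
  printed source values are mutually inconsistent with the rule's
  requirement $\theta_{NMDA} > \theta_{AMPA}$ (the third term needs
  $\theta_{AMPA} < S_J < \theta_{NMDA}$ to be realisable); the package
  adopts the ordering required by the rule's structure,
  $\theta_{NMDA} = 500 > \theta_{AMPA} = 150$.
* $\gamma_w = 5\times10^{-13}$ assumes a power-of-ten family like every
  sibling constant.
* $D_{base} = 0.2$ is chosen as `dopamine(0)`, the release level at zero
  prediction error, so that "dopamine above/below baseline" coincides
  exactly with positive/negative RPE.

# The classification experiment

Input neurons sit at coordinates $5, 15, \dots, 95$ on a one-dimensional
grid. Each trial selects one location uniformly at random and injects a
current of 70 through a Gaussian receptive field of standard deviation 30,
so neighbours receive proportionally less. The network's response is
winner-take-all on $S_J$ -- the same quantity the learning rule consumes,
which keeps decision and learning consistent. The category rule maps the
first five locations to the first postsynaptic neuron and the last five to
the second; reward is $+1$/$-1$ for correct/incorrect (a no-feedback
outcome, $R = 0$, is supported but never emitted by this task).

Session structure (`session_config()` defaults): 500 trials, accuracy
reported in blocks of 50 with "final accuracy" the last-block mean; trials
are 2000 steps with the stimulus on during steps $[100, 1100)$; membrane
state and transmission lines are reset between trials; initial plastic
weights are drawn uniformly from $[10, 40]$. The master seed spawns
independent child streams for the weight draw, the stimulus sequence and
the per-trial simulation, so that conditions differing only in
architecture or noise level see identical stimuli and initial weights --
the matched-control design that `run_matched_comparison()` and
`run_noise_sweep()` rely on.

Three of these protocol constants were genuinely open design choices:

* **Trial window.** The trial extends one full glutamate kernel length
  past stimulus offset. Ending the trial at stimulus offset would
  truncate exactly the slow-pathway prolongation that distinguishes the
  tripartite architecture (with a 1000-step trial the tripartite network
  was empirically indistinguishable from, or worse than, the bipartite
  one, because its mechanism never got to act).
* **Initial weights.** With mid-range initial weights (of order
  $w_{max}/2$) the postsynaptic drive starts two orders of magnitude
  above the activation thresholds; both postsynaptic cells then saturate
  $[S_J - \theta_{NMDA}]^+$, the $(w_{max} - w)$ factor systematically
  favours the trailing cell, and sessions *anti-learn* to well below
  chance. Starting small ($[10, 40]$) keeps early-session drive in the
  regime where the thresholds discriminate the winner from the loser and
  leaves ample headroom for potentiation.
* **Session length.** 500 trials; learning curves for well-behaved seeds
  plateau within roughly 300-400 trials under these conditions, and a
  full noise sweep over both architectures stays within a few minutes of
  CPU time.

# What the simulation shows, and its limits

At the defaults, over matched seeds: both architectures learn well above
chance in the noiseless condition; the tripartite network's mean final
accuracy exceeds the bipartite network's; per-step voltage noise barely
moves the bipartite network while it sharply degrades the tripartite one;
and the architecture gap at the highest noise level falls below its
noiseless value. These are exactly the quantities
`scripts/acceptance.R` recomputes and the acceptance tests assert.

Known limitations, found and characterised during development:

* **LTP-dominated weight drift.** With the default learning constants the
  potentiation and depression terms balance only near
  $w \approx 1700$ (of $w_{max} = 2000$), so over long sessions weights
  drift toward saturation, the two output columns homogenise, and
  winner margins shrink to a small fraction of $S_J$. This caps
  achievable accuracy (means over seeds around 0.6-0.7 rather than
  higher) and is the direct cause of the next point.
* **Noise fragility of the tripartite network.** Astrocytic glutamate is
  mostly common-mode (both astrocytes see the same IP3 field), inflating
  both $S_J$ values and further shrinking *relative* winner margins; the
  per-trial noise then randomises the winner, rewards become incoherent,
  and tripartite sessions under noise hover near chance rather than
  degrading gracefully.
* **Inter-seed variance.** Single sessions are highly variable (final
  accuracies from 0.3 to 1.0 across seeds); every reported accuracy is
  therefore a mean over at least 10 matched seeds, and single-run numbers
  should not be compared against band-style expectations.
* The synthetic stimulus generator emulates location coding with
  overlapping Gaussian receptive fields on a noiseless grid; it does not
  emulate input spike-train variability, receptor stochasticity, or any
  astrocyte-to-astrocyte coupling, so conclusions transfer to real
  recordings only at the level of architecture comparisons, not absolute
  accuracies.

# Reproducibility

All randomness flows from explicit seeds through base R's generator
(including inside the compiled trial loop), so equal configurations give
bit-identical sessions on a given platform. The compiled fast path is
cross-checked against an independent pure-R reference stepper in the test
suite, exact to floating-point roundoff, in both noiseless and noisy
conditions.
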