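---
title: "Input-dependent inhibitory plasticity in spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input-dependent inhibitory plasticity in spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(idipnet)
```

## The scientific problem

Neural circuits keep their overall activity within a narrow operating range
while individual neurons change their tuning with experience. Classical
homeostatic rules are *neuron-centered*: each cell is pushed toward its own
firing-rate set point. Several experimental observations — rapid emergence of
an alternative hippocampal place map when the established one is silenced,
inhibitory scaling that is decoupled from single postsynaptic cells, broad
adjustment of inhibition after sensory deprivation — point instead to
*network-centered* control, where the quantity under regulation is the
activity of the local network as a whole.

`idipnet` implements one candidate mechanism: **input-dependent inhibitory
plasticity (IDIP)**. Inhibitory interneurons are densely and broadly
connected to their local excitatory population, so the excitatory synaptic
input they receive is a proxy for network activity. Under IDIP each
inhibitory neuron `i` maintains a low-pass record of that input and scales
*all* of its outgoing inhibitory synapses by the deviation from a target:

* trace: `dy_i/dt = -y_i / tau_IDIP + sum_j gE_ij(t)`
* at each spike of neuron `i`: `dw_ji = eta * (y_i - theta_in)` for every
  outgoing weight `w_ji`.

The rule has a single global knob, the target input `theta_in`, and no
per-neuron rate set point: at the rule's fixed point the *spike-triggered
average* of `y_i` equals `theta_in`, which pins the summed (conductance-
weighted) activity of the presynaptic excitatory network while leaving the
distribution of that activity across neurons free. That freedom is what
distinguishes IDIP functionally from the neuron-centered inhibitory STDP
(iSTDP) baseline also shipped here, whose depression factor `alpha` imposes
the same target rate `alpha / (2 * tau)` on every excitatory cell.

### Units and the trace convention

All computation uses mV, ms, nS, megaohm and nA; `R[megaohm] * g[nS]` is
dimensionless up to a factor `1e-3` and `R[megaohm] * I[nA]` is directly mV.

The IDIP trace is the *leaky integral* of the conductance sum (units
nS·ms, reported as nS at the 1 ms step). Its fixed point under stationary
input is `tau_IDIP * <sum_j gE_ij>`. This convention is what anchors the
shipped targets: with `tau_IDIP = 160 ms`, `theta_in = 200 nS` in the
hippocampal model corresponds to a summed CA1 excitatory rate of about
110–125 Hz (a population mean near 1.2 Hz), and `theta_in = 550 nS` in the
recurrent model to a mean excitatory rate of a few Hz. Reading the trace
instead as a low-pass filter with unit DC gain (fixed point `<sum g>`, a
few nS in both models) would leave both targets unreachable by more than an
order of magnitude and the rule permanently depressing — the hundreds-of-nS
targets are only meaningful for the leaky-integral form. The same integrator
convention underlies the `v5` variant's rate estimator
(`x_est / tau_est` is the estimated rate).

## Simulation engine

Clocked simulation at `dt = 1 ms`:

* **Voltage** is integrated by forward Euler for conductance-based LIF
  neurons, `tau_m dV/dt = (V_rest - V) + R(gE(V_E - V) + gI(V_I - V) + I)`,
  with threshold `-50 mV`, reset to `-60 mV` and a 2 ms absolute refractory
  period during which the cell is held at rest and not integrated. The Euler
  step is clamped to `[V_I, V_E]` — the bounds that exact integration of the
  reversal-potential dynamics provably respects — so extreme conductances
  cannot destabilize the explicit scheme. A neuron already at or above
  threshold spikes without further integration.
* **Conductances** decay *exactly* (`g <- g * exp(-dt/tau)`): the conductance
  ODE is linear between spikes, so the exponential update is exact rather
  than an approximation. This matters quantitatively: at `tau_E = 5 ms` the
  exact update carries ~10% more mean conductance per unit presynaptic rate
  than the Euler factor `(1 - dt/tau)`, which shifts the recurrent model's
  equilibrium rate by about 1 Hz. Each presynaptic spike increments the
  postsynaptic conductance by `g_bar * W` (delta-pulse convention,
  `g_bar = 1 nS`).
* **Spike delivery** has a one-step delay: spikes detected at step `t` reach
  conductances at the start of step `t + 1`. No axonal delays.
* **Plasticity ordering**: traces are advanced with the current step's
  conductances and spikes first, then spike-triggered weight updates are
  applied, so a spike "sees" the trace including its own contribution.
* **Initial conditions**: conductances start at zero. The generic reference
  engine starts voltages at rest; the two model builders draw initial
  voltages uniformly between rest and threshold (seeded). The latter is a
  deliberate choice: the hippocampal inhibitory population is fully
  connected and receives *identical* input, so identical initial conditions
  lock it into perfectly synchronized volleys, and pulsed global inhibition
  cannot implement the graded lateral inhibition the balanced state needs.
* Synaptic traces (Hebbian, iSTDP, IDIP) use the Euler decay factor
  `(1 - dt/tau)`; only conductances use the exact factor.

The compiled engines (`src/engines.cpp`) mirror the plain-R reference
engine (`run_network()`) operation for operation; the test suite asserts
bitwise-identical spike logs, weights and traces between the two over
scripted-input runs of both models.

## The hippocampal CA3→CA1 model

A simulated mouse traverses a 1D annular track at constant speed (3 s
between adjacent field centers; one lap = 30 s). Ten CA3 cells receive
Gaussian place-tuned currents `I(p) = A_c * exp(-d(p, p0)^2 / (2 sigma^2))`
with `A_c = 200 pA` and `sigma = 6.54 a.u.`; `d` is the circular distance.
The track circumference is set to 100 a.u. (field spacing 10 a.u.), chosen
so the printed tuning width yields overlapping, tiled fields; it is a free
geometry parameter, configurable in `track_geometry()`.

One hundred CA1 excitatory cells form 10 groups tuned to the 10 fields.
Each CA1 cell receives the same Gaussian place current with a per-neuron
amplitude offset: `I_j(p) = A_c * (T(p - p0_group) + s_j)`, where the ten
offsets `s` per group are drawn once from Normal(0, 0.05) and independently
shuffled within each group (every group carries the same offset multiset).
CA3 additionally projects to every CA1 excitatory cell with initial weight
`theta_homeo / N_CA3 = 0.52`, so the summed feedforward weight starts
exactly at the homeostatic target; this projection is plastic under a
symmetric Hebbian rule with a soft per-weight bound (`w_max = 1.5`) and a
homeostatic term that pulls each cell's summed input weight toward
`theta_homeo = 5.2`, implementing competition among that cell's inputs.

Excitatory and inhibitory CA1 populations are fully and bidirectionally
connected (E→I fixed at 2.0; I→E initialized at 1e-3 and plastic under
additive IDIP, clipped at zero, no upper bound). The inhibitory cells
receive a uniform tonic current of 0.5 nA (50 mV of drive at 100 megaohm),
making them fire tonically, asynchronously and without spatial tuning; the
excitatory feedback modulates this baseline and IDIP sets the weight scale
of the inhibition it feeds back. This tonic term is load-bearing: without
it the inhibitory population is driven solely by its (identical) excitatory
input and collapses into synchronized volleys, between which excitatory
cells escape — the IDIP trace then never reaches target and the inhibitory
weights grow without bound.

With these ingredients the exploration phase self-organizes: on lap 1
(plasticity off) every cell fires within its field with amplitudes ordered
by `s`; once Hebbian plasticity and IDIP switch on, inhibition rises until
the spike-triggered trace sits at `theta_in = 200 nS`, and the cells whose
offsets fall below the margin that this inhibition level sets become
silent. The split is amplified by the Hebbian loop (silent cells lose their
feedforward potentiation) and is identical in every group because the
offset multiset is. The number of active cells grows with `theta_in`.

Protocols:

* `run_silencing()` clamps all labeled active cells at rest for one lap
  (idealized optogenetic inhibition: no spikes, conductances keep
  decaying), then releases them. With IDIP on, inhibition re-converges to
  the same network rate carried by the previously silent cells; with IDIP
  frozen at silencing onset, the alternative map barely activates. The
  map-level comparison uses the network population rate per phase — during
  the baseline lap only the original map is active and during the
  silencing lap only the alternative one, so the population rate is the
  respective map's activity, and it is the quantity IDIP conserves.
  Member-mean rates per map are reported alongside.
* `run_consolidation()` repeats 4 silencing laps + 1 test lap for 10
  trials. During silencing laps the alternative cells fire co-actively
  with CA3 and potentiate their feedforward weights; over trials the
  original map's test-lap rate declines and the alternative's grows.
  Freezing the CA3→CA1 weights (`hebbian_on = FALSE`) abolishes both
  trends — consolidation lives in the feedforward plasticity. In this
  implementation the trend saturates after roughly half the trials; the
  direction, not the saturation point, is the tested claim.

One caveat: because the interneurons are dominated by tonic drive, the
purely fast (disinhibition-only) component of remapping is weak here — with
IDIP frozen, the alternative map's activation during silencing is near
zero rather than partial. The compensation dynamics with IDIP on are
unaffected.

## The sparse recurrent model

Eighty excitatory and 20 inhibitory LIF neurons with fixed in-degrees:
exactly `N_E * p_EE = 8` excitatory and `N_I * p_EI = 5` inhibitory inputs
per excitatory neuron, `N_E * p_IE = 20` excitatory inputs per inhibitory
neuron, no self-connections, no I→I synapses by default (`p_II = 0` is a
config toggle). Every neuron draws exactly 20 of the 100 external Poisson
units (10 Hz each). Weights are lognormal; `mu = 1.0` and `sigma = 0.1`
are interpreted as the *mean and standard deviation of the weight
distribution itself* (the builder derives `meanlog`/`sdlog`). Input weights
are scaled by 2.5 for both excitatory and inhibitory targets; initial
inhibitory weights are 0.1 times a draw from the same family. Only I→E
weights are plastic, under IDIP with a multiplicative bound
(`w <- w + (w_max - w) dw` for potentiation, `w <- w + w dw` for
depression), or under additive iSTDP as the neuron-centered baseline.

Without plasticity the network is pathologically active (tens of Hz,
synchronous). With IDIP enabled at 15 s, inhibitory weights grow until the
spike-triggered trace sits at `theta_in = 550 nS`; the excitatory
population settles near 5 Hz with a heterogeneous, heavy-tailed rate
distribution — the heterogeneity is inherited from the random in-degrees
and lognormal weights, not imposed by the rule.

**The inhibitory weight bound.** The bound's printed companion constants
are mutually inconsistent in this architecture: with `w_max = 1.0` the
inhibitory weights pin at the bound while the trace is still ~40% above
target (the network saturates near 16 Hz), whereas the 550 nS fixed point
requires mean inhibitory weights near 1.9 — about twice the mean excitatory
weight, mirroring the 2.0 E/I weight ratio of the hippocampal model. The
package therefore ships `w_max = 5.0`, a non-binding bound under which the
rule settles at its actual fixed point (converged weights ~1.9, maximum
~2.4); the multiplicative form is kept because near-binding bounds bias
the equilibrium (the asymmetric damping of potentiation versus depression
holds the spike-triggered trace a few percent above target). Equilibrium
rates are insensitive to the learning rate (1e-6 and the default 1e-7 give
the same equilibrium; only the approach speed differs), consistent with
the rule's fixed-point character.

Protocols: `run_stabilization()` (convergence = windowed mean rate changing
< 2% between consecutive 50 s windows, or a fixed duration),
`sweep_theta_connectivity()` (converged rate vs `theta_in` and `p_EI`;
rising in the target, falling in inhibitory connectivity, flat in `p_EE`),
`run_subset_drive()` (+50% external weights to a subset from run start:
the subset stays elevated while the network mean is maintained),
`compute_rank_report()` (Spearman rank correlation of per-neuron rates in
15 s bins against the first, pre-plasticity bin; ties by average ranks,
empty or zero-variance bins reported as `NA`), and `run_memory_task()`
(stabilize to 600 s → multiply existing recurrent synapses within a random
12-cell ensemble by 5 → re-converge to 1200 s → +50% external weights on 2
ensemble cells; 50 s probe windows flank each event). Because IDIP imposes
no per-neuron set point, the potentiated ensemble keeps an elevated rate
after re-convergence and the cue re-activates non-cued members relative to
the rest of the network; under iSTDP the elevation is squeezed back toward
the common set point and recall fidelity drops. Recall reactivation is
measured network-relative (ensemble/rest ratio) because the global rule
compensates the cue-driven excitation at the population level.

## What the tests do and do not show

All inputs are synthetic by construction (Gaussian place currents, Poisson
drive, seeded random wiring); the generator defaults *are* the study
conditions, and the test suite plus `scripts/acceptance.R` recompute every
quantitative claim from scratch: the ~5.2–5.3 Hz converged recurrent rate
(10 seeds, 2000 s each, final 100 s), the 550 nS and 200 nS spike-triggered
fixed points (within ~1–2%), the 60/40 active/silent split at
`theta_in = 200 nS`, the silencing compensation and its frozen-IDIP
control, the consolidation trends and their Hebbian ablation, rank
preservation under IDIP versus iSTDP on matched seeds, and memory
persistence/recall. Scaled-down problem sizes are used where the full
protocol adds nothing: explorations run 30 laps (the split and the fixed
point are stable long before 100), rank and subset runs 600 s, and sweeps
use 2 seeds per cell at 400 s.

These are demonstrations about the *model class*, not about tissue: point
neurons, one interneuron class, no conduction delays, no short-term
plasticity, deterministic place currents, and a single 1D environment. The
hippocampal model's interneuron desynchronization relies on tonic drive
rather than intrinsic heterogeneity; real circuits have both. The
consolidation effect size depends on the offset spread and saturates
within a few trials. Fully deterministic runs (identical seeds) are exact
to the bit, which the determinism tests exploit; nothing in the dynamics
is stochastic except the Poisson sources and the seeded build.
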