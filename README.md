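# idipnet

Spiking-network models of **input-dependent inhibitory plasticity (IDIP)** —
a network-centered homeostatic rule for conductance-based leaky
integrate-and-fire (LIF) circuits — with complete, tested implementations of
a hippocampal CA3→CA1 place-cell model and a sparse random recurrent
network, the experimental protocols that probe them, and a neuron-centered
inhibitory STDP (iSTDP) baseline for comparison.

## The rule

Inhibitory interneurons are densely connected to their local excitatory
network, so their synaptic input tracks network activity. Under IDIP each
inhibitory neuron *i* keeps a leaky integral of its summed excitatory
conductance,

    dy_i/dt = -y_i / tau_IDIP + sum_j gE_ij(t),

and, whenever it spikes, adjusts **all** of its outgoing inhibitory weights
by the deviation from a target input:

    dw_ji = eta * (y_i - theta_in).

At the fixed point the spike-triggered average of `y_i` equals `theta_in`:
the rule clamps what the inhibitory population collectively senses — the
summed activity of the excitatory network — without imposing any per-neuron
firing-rate set point. That single difference from neuron-centered rules
(iSTDP drives every excitatory cell to the same rate `alpha / (2 tau)`)
produces the package's headline behaviors: active/silent place-cell
competition and rapid homeostatic remapping in the hippocampal model;
stabilization of runaway recurrent dynamics while preserving firing-rate
heterogeneity, stimulus representation, rank order, and persistent memory
traces in the recurrent model.

Who this is for: computational neuroscientists studying homeostatic
plasticity and E/I balance, and anyone needing a small, fast, fully seeded
conductance-based LIF network simulator in R (the hot loops are in C++ via
Rcpp; a plain-R reference engine is kept bitwise-equivalent for toy circuits
and verification).

## Worked example

```r
library(idipnet)

## sparse recurrent network: 80E/20I, lognormal weights, Poisson drive
set.seed(1)
net <- build_recurrent_net(recurrent_net_spec(), seed = 1)
st  <- run_stabilization(net, duration = 2000000)   # IDIP on at 15 s
st$final_rate     # mean excitatory rate over the final 100 s
st$y_spike_avg    # spike-triggered IDIP trace at convergence
st$net

## hippocampal CA3 -> CA1 place-cell model: 30 exploration laps
hip <- build_hippocampal_net(seed = 3)
ex  <- run_exploration(hip, n_laps = 30)
ex$net
sil <- run_silencing(ex$net)     # silence the active map for one lap
sil$rates
```

Output:

```
converged mean excitatory rate: 5.21 Hz
spike-triggered IDIP trace:     544.1 nS (target 550)
<recurrent_net> 80E/20I + 100 Poisson units, t = 2000.0 s, mean I->E weight 1.95

<hippocampal_net> CA3 10 -> CA1 100E/20I, t = 900.0 s, 60 active / 40 silent
spike-triggered IDIP trace:     200.0 nS (target 200)
    phase lap original alternative population
1     off   1     1.89      0.0000       1.13
2      on   2     0.00      2.8183       1.13
3 release   3     1.88      0.0208       1.14
```

Reading the numbers: the recurrent network starts in a pathological
high-activity regime and IDIP brings it to a ~5.2 Hz mean with the
inhibitory input trace pinned at its 550 nS target. In the hippocampal
model, exploration splits every place-tuned group into active and silent
cells (60/40 at the 200 nS target). Silencing the active map for one lap
(`on`) hands the *entire network rate* (population column, 1.13 Hz) over to
the previously silent alternative map — network-level homeostasis — and the
original map re-emerges on release. Re-running the silencing with
`with_idip = FALSE` leaves the alternative map silent.

Other protocols: `run_consolidation()` (repeated silencing consolidates the
alternative map via CA3→CA1 Hebbian plasticity),
`sweep_theta_connectivity()`, `run_subset_drive()`, `compute_rank_report()`
and `run_memory_task()` for the recurrent model, and `ensemble_run()` for
multi-seed summaries. A thin command-line wrapper lives at
`inst/cli/idipnet.R`:

```sh
Rscript inst/cli/idipnet.R recurrent stabilize --seed 1 --duration 600 --out out/
Rscript inst/cli/idipnet.R hippocampus explore --seed 3 --laps 30 --out out/
```

Model parameters are structured-text configs (`inst/extdata/*.yaml`),
hashed into every output so results from different configurations refuse to
aggregate. The methods vignette (`vignettes/idip-networks.Rmd`) documents
the equations, unit conventions, integrator choices and the design
decisions behind both models.

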