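# Hippocampal CA3 -> CA1 network defaults.
# Units: mV, ms, nS, megaohm, nA, a.u. (track).
populations:
  n_ca3: 10        # CA3 excitatory cells (one per place field)
  n_e: 100         # CA1 excitatory cells
  n_i: 20          # CA1 inhibitory cells
  n_groups: 10     # equally sized place-tuned CA1 groups
track:
  n_fields: 10
  circumference: 100.0   # a.u.; 10 a.u. between field centers
  sigma_pc: 6.54         # tuning width (a.u.)
  a_c: 0.2               # place current amplitude (nA = 200 pA)
  secs_between_fields: 3 # travel time between adjacent centers
tuning:
  offset_sd: 0.05        # s ~ Normal(0, 0.05), shuffled per group
currents:
  i_ex_e: 0.01           # uniform current to excitatory cells (nA)
  i_ex_i: 0.5            # uniform tonic current to inhibitory cells (nA)
weights:
  w_ie: 2.0              # E -> I synaptic weight (fixed)
  w_ei: 1.0e-3           # initial I -> E synaptic weight
idip:
  eta: 1.0e-5            # learning rate (1/(ms*nS))
  theta_in: 200.0        # inhibitory neuron target input (nS)
  tau: 160.0             # trace decay constant (ms)
hebbian:
  eta_hebb: 1.0e-3       # Hebbian term learning rate (1/ms)
  eta_homeo: 1.0e-4      # homeostatic term learning rate (1/ms)
  theta_homeo: 5.2       # target summed input weight
  w_max: 1.5             # maximum E -> E synaptic weight (soft bound)
  tau: 20.0              # learning window time constant (ms)
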