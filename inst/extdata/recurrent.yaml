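# Sparse random recurrent network defaults.
# Units: mV, ms, nS, megaohm, nA.
populations:
  n_e: 80          # excitatory neurons
  n_i: 20          # inhibitory neurons
  n_ex: 100        # external Poisson units
connectivity:      # in-degrees are exact: k = round(p * pool size)
  p_ee: 0.1
  p_ie: 0.25
  p_ei: 0.25
  p_ii: 0.0
  p_ex: 0.2
input:
  rate: 10.0       # mean Poisson firing rate (Hz)
weights:
  mu: 1.0          # mean of the lognormal weight distribution
  sigma_wrec: 0.1  # s.d. of the recurrent weight distribution
  sigma_win: 0.1   # s.d. of the input weight distribution
  input_gain: 2.5  # multiplier on all external input weights
  wi_we_ratio: 0.1 # initial inhibitory/excitatory weight ratio
idip:
  eta: 1.0e-7      # learning rate (1/(ms*nS))
  theta_in: 550.0  # inhibitory neuron target input (nS)
  tau: 160.0       # trace decay constant (ms)
  w_max: 5.0       # maximum I -> E weight (multiplicative bound; non-binding)
istdp:
  eta: 5.0e-5      # learning rate
  alpha: 0.2       # depression factor (target rate alpha / (2 tau))
  tau: 20.0        # learning window time constant (ms)
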