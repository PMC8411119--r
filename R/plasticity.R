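#' Input-dependent inhibitory plasticity (IDIP)
#'
#' Each inhibitory neuron `i` maintains a leaky integral of its summed
#' excitatory synaptic conductance,
#' `dy_i/dt = -y_i / tau + sum_j gE_ij(t)`,
#' whose fixed point under stationary input is `tau * <sum_j gE_ij>` (units
#' nS*ms; reported in nS at the 1 ms integration step, the convention in
#' which the shipped targets `theta_in` = 200 and 550 nS are expressed).
#' Whenever neuron `i` spikes, every outgoing inhibitory weight is adjusted by
#' `dw = eta * (y_i - theta_in)`: inhibition strengthens when the local
#' excitatory network drives the inhibitory population above target and
#' weakens below it. There is no per-neuron firing-rate set point.
#'
#' Weight application is either `"additive"` (clipped below at 0, optionally
#' above at `w_max`; used by the hippocampal model, which has no upper bound)
#' or `"multiplicative"` (`w <- w + (w_max - w)*dw` for potentiation and
#' `w <- w + w*dw` for depression, which confines weights to `[0, w_max]`;
#' used by the recurrent model).
#'
#' Variants of the rule (`variant`):
#' \describe{
#'   \item{`"base"`}{as above.}
#'   \item{`"v1"`}{the trace integrates the conductance scaled by the driving
#'     force, `sum_j gE_ij * (vE - V_i)` (units nS*mV*ms); `theta_in` must be
#'     rescaled accordingly. The shipped default multiplies the base target by
#'     a nominal 10 mV driving-force scale so the fixed-point activity matches
#'     the base rule's.}
#'   \item{`"v2"`}{the spike indicator is replaced by a synaptic trace `x_i`
#'     (time constant `tau_st`) and weights update every step by
#'     `eta * (y_i - theta_in) * x_i * dt`; with `tau_st -> 0` and
#'     `eta = eta_base / tau_st` this approaches the base rule.}
#'   \item{`"v3"`}{the trace integrates excitatory minus inhibitory
#'     conductance (for networks with inhibitory-to-inhibitory synapses).}
#'   \item{`"v4"`}{instead of weights, the spiking neuron's firing threshold
#'     moves by `eta * (y_i - theta_in)` (eta in mV/nS), confined to
#'     `[v_rest + 1, 0]` mV so units stay functional.}
#'   \item{`"v5"`}{the target input is replaced by a target firing rate
#'     `theta_x`; a running estimator `dx_est/dt = -x_est/tau_est + S(t)`
#'     yields the rate as `x_est/tau_est`, and spikes update weights by
#'     `eta * (x_est/tau_est - theta_x)`.}
#' }
#'
#' @param n_inh Number of inhibitory neurons carrying the rule.
#' @param eta Learning rate (1/(ms*nS) against the trace units).
#' @param theta_in Target input (nS; nS*mV for `"v1"`).
#' @param tau Trace time constant (ms).
#' @param update `"additive"` or `"multiplicative"` weight application.
#' @param w_max Upper weight bound (required for `"multiplicative"`).
#' @param variant One of `"base"`, `"v1"`..`"v5"`.
#' @param tau_st Synaptic trace time constant for `"v2"` (ms).
#' @param tau_est,theta_x Rate-estimator time constant (ms) and target rate
#'   (spikes/ms) for `"v5"`.
#' @return An object of class `idip_rule` holding the traces as state.
#' @export
idip_rule <- function(n_inh, eta = 1e-5, theta_in = 200, tau = 160,
                      update = c("additive", "multiplicative"), w_max = Inf,
                      variant = c("base", "v1", "v2", "v3", "v4", "v5"),
                      tau_st = 5, tau_est = 1000, theta_x = 5 / 1000) {
  update <- match.arg(update)
  variant <- match.arg(variant)
  if (update == "multiplicative" && !is.finite(w_max)) {
    stop("multiplicative IDIP requires a finite w_max")
  }
  structure(list(
    n = as.integer(n_inh), eta = eta, theta_in = theta_in, tau = tau,
    update = update, w_max = w_max, variant = variant,
    tau_st = tau_st, tau_est = tau_est, theta_x = theta_x,
    y = rep(0, n_inh), x = rep(0, n_inh), x_est = rep(0, n_inh)
  ), class = "idip_rule")
}

#' Advance the IDIP input trace by one step
#'
#' Euler step of the trace equation; for variants `"v2"` and `"v5"` the
#' auxiliary spike traces are advanced here too (decayed, then incremented by
#' 1 per spike, so that a spike in this step is visible to the weight update).
#'
#' @param state An [idip_rule()].
#' @param g_exc_sum Summed excitatory conductance onto each inhibitory neuron
#'   at this step (nS).
#' @param dt Time step (ms).
#' @param g_inh_sum Summed inhibitory conductance (nS), used by `"v3"`.
#' @param v_post Inhibitory membrane potentials (mV), used by `"v1"`.
#' @param v_rev_exc Excitatory reversal potential (mV), used by `"v1"`.
#' @param spikes Logical spike vector for this step (trace variants).
#' @return The updated rule state.
#' @export
idip_update_trace <- function(state, g_exc_sum, dt = 1, g_inh_sum = 0,
                              v_post = NULL, v_rev_exc = 0, spikes = NULL) {
  g_exc_sum <- rep_len(g_exc_sum, state$n)
  if (length(g_exc_sum) != state$n) stop("trace/input shape mismatch")
  input <- switch(state$variant,
    v1 = {
      if (is.null(v_post)) stop("variant v1 needs the inhibitory membrane potentials")
      g_exc_sum * (v_rev_exc - v_post)
    },
    v3 = g_exc_sum - rep_len(g_inh_sum, state$n),
    g_exc_sum
  )
  state$y <- state$y + dt * (-state$y / state$tau + input)
  if (state$variant == "v2") {
    state$x <- state$x * (1 - dt / state$tau_st)
    if (!is.null(spikes)) state$x[spikes] <- state$x[spikes] + 1
  }
  if (state$variant == "v5") {
    state$x_est <- state$x_est * (1 - dt / state$tau_est)
    if (!is.null(spikes)) state$x_est[spikes] <- state$x_est[spikes] + 1
  }
  state
}

#' Apply the IDIP weight (or threshold) update
#'
#' For each spiking inhibitory neuron `i`, every outgoing weight in column
#' `i` of `w` receives the signed update `eta * (y_i - theta_in)` under the
#' rule's weight application scheme. Variant `"v2"` updates all columns every
#' step, scaled by the synaptic trace and `dt`; variant `"v4"` returns
#' per-neuron threshold shifts instead of touching `w`.
#'
#' @param state An [idip_rule()] whose traces are current for this step.
#' @param spiking Logical vector (or integer indices) of inhibitory spikes.
#' @param w Outgoing inhibitory weight matrix, `n_post x n_inh`.
#' @param mask Optional logical connectivity mask of the same shape; only
#'   masked-in synapses are updated.
#' @param dt Time step (ms), used by the per-step variant `"v2"`.
#' @return A list with the updated `w` and, for `"v4"`, a vector `dtheta` of
#'   threshold shifts (zero elsewhere).
#' @export
idip_on_spike <- function(state, spiking, w, mask = NULL, dt = 1) {
  if (is.logical(spiking)) spiking <- which(spiking)
  n_inh <- ncol(w)
  stopifnot(n_inh == state$n)
  dtheta <- NULL

  if (state$variant == "v2") {
    dw <- state$eta * (state$y - state$theta_in) * state$x * dt
    cols <- which(dw != 0)
  } else if (state$variant == "v4") {
    dtheta <- rep(0, n_inh)
    dtheta[spiking] <- state$eta * (state$y[spiking] - state$theta_in)
    return(list(w = w, dtheta = dtheta))
  } else if (state$variant == "v5") {
    dw <- rep(0, n_inh)
    dw[spiking] <- state$eta * (state$x_est[spiking] / state$tau_est - state$theta_x)
    cols <- spiking
  } else {
    dw <- rep(0, n_inh)
    dw[spiking] <- state$eta * (state$y[spiking] - state$theta_in)
    cols <- spiking
  }
  if (length(cols) == 0L || ncol(w) == 0L || nrow(w) == 0L) {
    return(list(w = w, dtheta = dtheta))
  }

  for (i in cols) {
    col <- w[, i]
    on <- if (is.null(mask)) TRUE else mask[, i]
    d <- dw[i]
    if (state$update == "additive") {
      col[on] <- col[on] + d
    } else if (d > 0) {
      col[on] <- col[on] + (state$w_max - col[on]) * d
    } else {
      col[on] <- col[on] + col[on] * d
    }
    w[, i] <- col
  }
  w[w < 0] <- 0
  if (is.finite(state$w_max)) w[w > state$w_max] <- state$w_max
  list(w = w, dtheta = dtheta)
}

#' Symmetric Hebbian plasticity with a homeostatic weight-sum constraint
#'
#' Feedforward excitatory rule used on the CA3-to-CA1 projection. Each neuron
#' carries a synaptic trace `tau_hebb dx/dt = -x + S(t)` (incremented by 1
#' per spike) and the weight from presynaptic `i` to postsynaptic `j` follows
#' `dw_ji/dt = eta_hebb * (w_max - w_ji) * x_i * x_j
#'            - eta_homeo * (sum_i w_ji - theta_homeo)`,
#' integrated every step and clipped below at 0. The Hebbian term softly
#' saturates at `w_max`; the homeostatic term pulls each postsynaptic
#' neuron's summed input weight toward `theta_homeo`, implementing
#' competition among that neuron's inputs.
#'
#' @param n_pre,n_post Population sizes.
#' @param eta_hebb,eta_homeo Learning rates (1/ms).
#' @param theta_homeo Target summed input weight per postsynaptic neuron.
#' @param w_max Soft upper bound of a single weight.
#' @param tau Trace time constant (ms).
#' @return An object of class `hebbian_rule`.
#' @export
hebbian_rule <- function(n_pre, n_post, eta_hebb = 1e-3, eta_homeo = 1e-4,
                         theta_homeo = 5.2, w_max = 1.5, tau = 20) {
  structure(list(
    n_pre = as.integer(n_pre), n_post = as.integer(n_post),
    eta_hebb = eta_hebb, eta_homeo = eta_homeo,
    theta_homeo = theta_homeo, w_max = w_max, tau = tau,
    x_pre = rep(0, n_pre), x_post = rep(0, n_post)
  ), class = "hebbian_rule")
}

#' One step of the Hebbian + homeostatic rule
#'
#' @param state A [hebbian_rule()].
#' @param pre_spikes,post_spikes Logical spike vectors for this step.
#' @param w Weight matrix `n_post x n_pre`.
#' @param dt Time step (ms).
#' @param mask Optional connectivity mask.
#' @return A list with updated `w` and `state`.
#' @export
hebbian_step <- function(state, pre_spikes, post_spikes, w, dt = 1, mask = NULL) {
  state$x_pre <- state$x_pre * (1 - dt / state$tau)
  state$x_post <- state$x_post * (1 - dt / state$tau)
  state$x_pre[pre_spikes] <- state$x_pre[pre_spikes] + 1
  state$x_post[post_spikes] <- state$x_post[post_spikes] + 1

  hebb <- state$eta_hebb * (state$w_max - w) * tcrossprod(state$x_post, state$x_pre)
  homeo <- state$eta_homeo * (.rowSums(w, nrow(w), ncol(w)) - state$theta_homeo)
  dw <- hebb - homeo  # homeo recycles down columns: same value across a row
  if (!is.null(mask)) dw[!mask] <- 0
  w <- w + dt * dw
  w[w < 0] <- 0
  list(w = w, state = state)
}

#' Inhibitory spike-timing-dependent plasticity (neuron-centered baseline)
#'
#' The symmetric inhibitory STDP rule: presynaptic (inhibitory) and
#' postsynaptic (excitatory) neurons carry traces
#' `tau dx/dt = -x + S(t)`; when presynaptic neuron `i` spikes,
#' `w_ji <- w_ji + eta * (x_j - alpha)` for all targets `j`, and when
#' postsynaptic neuron `j` spikes, `w_ji <- w_ji + eta * x_i` for all of its
#' inhibitory inputs. The depression factor `alpha` sets a per-neuron target
#' firing rate of `alpha / (2 * tau)` (2.5 spikes/s per 0.1 of alpha at
#' tau = 20 ms), making the rule neuron-centered: every excitatory neuron is
#' pushed toward the same rate. Weights are clipped below at 0; updates are
#' additive as printed.
#'
#' @param n_pre Number of inhibitory (presynaptic) neurons.
#' @param n_post Number of excitatory (postsynaptic) neurons.
#' @param eta Learning rate.
#' @param alpha Depression factor.
#' @param tau Trace time constant (ms).
#' @return An object of class `istdp_rule`.
#' @export
istdp_rule <- function(n_pre, n_post, eta = 5e-5, alpha = 0.2, tau = 20) {
  structure(list(
    n_pre = as.integer(n_pre), n_post = as.integer(n_post),
    eta = eta, alpha = alpha, tau = tau,
    x_pre = rep(0, n_pre), x_post = rep(0, n_post)
  ), class = "istdp_rule")
}

#' Advance iSTDP traces and apply spike-triggered updates
#'
#' Traces are decayed and incremented for this step's spikes first, so a
#' spike sees the trace including its own increment; weight updates follow.
#'
#' @param state An [istdp_rule()].
#' @param pre_spikes,post_spikes Logical spike vectors for this step.
#' @param w Weight matrix `n_post x n_pre` (excitatory rows, inhibitory cols).
#' @param dt Time step (ms).
#' @param mask Optional connectivity mask.
#' @return A list with updated `w` and `state`.
#' @export
istdp_step <- function(state, pre_spikes, post_spikes, w, dt = 1, mask = NULL) {
  state$x_pre <- state$x_pre * (1 - dt / state$tau)
  state$x_post <- state$x_post * (1 - dt / state$tau)
  state$x_pre[pre_spikes] <- state$x_pre[pre_spikes] + 1
  state$x_post[post_spikes] <- state$x_post[post_spikes] + 1

  if (any(pre_spikes)) {
    for (i in which(pre_spikes)) {
      on <- if (is.null(mask)) TRUE else mask[, i]
      w[on, i] <- w[on, i] + state$eta * (state$x_post[on] - state$alpha)
    }
  }
  if (any(post_spikes)) {
    for (j in which(post_spikes)) {
      on <- if (is.null(mask)) TRUE else mask[j, ]
      w[j, on] <- w[j, on] + state$eta * state$x_pre[on]
    }
  }
  w[w < 0] <- 0
  list(w = w, state = state)
}
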