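#' Leaky integrate-and-fire membrane parameters
#'
#' Parameter set for a single-compartment conductance-based LIF population.
#' Defaults are the standard values used by both shipped network models.
#'
#' @param v_rest Resting membrane potential (mV); also the reset value.
#' @param theta_m Spike threshold (mV); must exceed `v_rest`.
#' @param r_m Membrane resistance (megaohm).
#' @param tau_m Membrane time constant (ms).
#' @param t_ref Absolute refractory period (ms); the neuron is clamped at
#'   `v_rest` and cannot be stimulated while refractory.
#' @param i_ex Baseline external current (nA).
#' @param v_rev_exc,v_rev_inh Excitatory and inhibitory reversal potentials
#'   (mV) seen by this population.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(v_rest = -60, theta_m = -50, r_m = 100,
                          tau_m = 20, t_ref = 2, i_ex = 0,
                          v_rev_exc = 0, v_rev_inh = -80) {
  stopifnot(tau_m > 0, t_ref >= 0, r_m > 0)
  if (theta_m <= v_rest) {
    stop("spike threshold theta_m must exceed the resting potential v_rest")
  }
  structure(list(v_rest = v_rest, theta_m = theta_m, r_m = r_m,
                 tau_m = tau_m, t_ref = t_ref, i_ex = i_ex,
                 v_rev_exc = v_rev_exc, v_rev_inh = v_rev_inh),
            class = "neuron_params")
}

#' A population of LIF neurons
#'
#' @param n Number of neurons.
#' @param params A [neuron_params()] object shared by the population.
#' @param v Initial membrane potentials (mV); defaults to `v_rest` for every
#'   neuron (conductances and voltages start from rest unless overridden).
#' @return An object of class `neuron_population` with fields `v` (mV),
#'   `refractory_remaining` (ms), `theta` (per-neuron thresholds, mV; equal to
#'   `params$theta_m` unless a threshold-plasticity rule moves them),
#'   `clamped` (logical; silenced neurons are held at rest and cannot spike)
#'   and `size`.
#' @export
neuron_population <- function(n, params = neuron_params(), v = NULL) {
  stopifnot(inherits(params, "neuron_params"), n >= 1)
  if (is.null(v)) v <- rep(params$v_rest, n)
  stopifnot(length(v) == n)
  structure(list(params = params, v = v,
                 refractory_remaining = rep(0, n),
                 theta = rep(params$theta_m, n),
                 clamped = rep(FALSE, n),
                 size = as.integer(n)),
            class = "neuron_population")
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population> %d neurons, V in [%.2f, %.2f] mV, %d refractory\n",
              x$size, min(x$v), max(x$v), sum(x$refractory_remaining > 0)))
  invisible(x)
}

#' One forward-Euler membrane step
#'
#' Advances the membrane equation
#' `tau_m dV/dt = (v_rest - V) + R*(gE*(vE - V) + gI*(vI - V) + I)`
#' by `dt` for all non-refractory, non-clamped neurons. Neurons reaching
#' threshold are marked as spiking, reset to `v_rest` and enter the
#' refractory period, during which the voltage is held at rest and not
#' integrated (synaptic conductances keep decaying in the projections).
#'
#' @param pop A [neuron_population()].
#' @param g_exc,g_inh Per-neuron summed excitatory/inhibitory conductance (nS).
#' @param i_ext Per-neuron external current (nA), added to `params$i_ex`.
#' @param dt Time step (ms).
#' @param time Optional current time (ms), used only in diagnostics.
#' @return A list with the updated `pop` and a logical vector `spiked`.
#' @export
step_membrane <- function(pop, g_exc = 0, g_inh = 0, i_ext = 0, dt = 1,
                          time = NA_real_) {
  p <- pop$params
  n <- pop$size
  g_exc <- rep_len(g_exc, n); g_inh <- rep_len(g_inh, n)
  i_ext <- rep_len(i_ext, n) + p$i_ex
  if (any(!is.finite(pop$v)) || any(!is.finite(g_exc)) || any(!is.finite(g_inh))) {
    bad <- which(!is.finite(pop$v) | !is.finite(g_exc) | !is.finite(g_inh))[1L]
    stop(sprintf("non-finite state for neuron %d at t = %s ms", bad, format(time)))
  }
  if (any(g_exc < 0) || any(g_inh < 0)) stop("negative conductance")
  stopifnot(dt > 0)

  refr <- pop$refractory_remaining > 0
  free <- !refr & !pop$clamped
  v <- pop$v
  # a neuron already at or above threshold spikes without further integration
  at_theta <- free & (v >= pop$theta)
  free <- free & !at_theta
  # R[megaohm] * g[nS] is dimensionless up to 1e-3; R[megaohm] * I[nA] is mV
  drive <- (p$v_rest - v) +
    1e-3 * p$r_m * g_exc * (p$v_rev_exc - v) +
    1e-3 * p$r_m * g_inh * (p$v_rev_inh - v) +
    p$r_m * i_ext
  v[free] <- v[free] + (dt / p$tau_m) * drive[free]
  # reversal-bounded dynamics: keep the Euler step inside [V_I, V_E]
  v <- pmin(pmax(v, p$v_rev_inh), p$v_rev_exc)

  spiked <- at_theta | (free & (v >= pop$theta))
  v[spiked] <- p$v_rest
  pop$refractory_remaining[spiked] <- p$t_ref
  pop$refractory_remaining[refr] <- pmax(pop$refractory_remaining[refr] - dt, 0)
  v[refr | pop$clamped] <- p$v_rest
  pop$v <- v
  list(pop = pop, spiked = spiked)
}
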