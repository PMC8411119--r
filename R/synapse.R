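#' Conductance-based synapse parameters
#'
#' @param g_bar Basic conductance unit (nS); a presynaptic spike through a
#'   weight `W` increments the postsynaptic conductance by `g_bar * W`.
#' @param v_rev Reversal potential (mV): 0 for excitatory, -80 for inhibitory
#'   projections by convention.
#' @param tau_syn Conductance decay time constant (ms): 5 for AMPA-type,
#'   10 for GABA-type.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(g_bar = 1, v_rev = 0, tau_syn = 5) {
  stopifnot(tau_syn > 0, g_bar >= 0)
  structure(list(g_bar = g_bar, v_rev = v_rev, tau_syn = tau_syn),
            class = "synapse_params")
}

#' Excitatory / inhibitory parameter presets
#' @rdname synapse_params
#' @export
exc_synapse <- function(g_bar = 1) synapse_params(g_bar, v_rev = 0, tau_syn = 5)

#' @rdname synapse_params
#' @export
inh_synapse <- function(g_bar = 1) synapse_params(g_bar, v_rev = -80, tau_syn = 10)

#' A weighted projection between two populations
#'
#' Holds a dense `n_post x n_pre` weight matrix, a boolean connectivity mask
#' and the per-postsynaptic-neuron summed conductance state. Weights are
#' non-negative and zero off the mask.
#'
#' @param n_pre,n_post Population sizes.
#' @param weight Scalar or `n_post x n_pre` matrix of initial weights
#'   (dimensionless multiples of `g_bar`).
#' @param params A [synapse_params()] object.
#' @param mask Logical `n_post x n_pre` connectivity matrix (default: full).
#' @return An object of class `synaptic_projection` with fields `w`, `mask`,
#'   `g` (per-post summed conductance, nS) and `params`.
#' @export
synaptic_projection <- function(n_pre, n_post, weight = 0,
                                params = exc_synapse(), mask = NULL) {
  stopifnot(inherits(params, "synapse_params"))
  w <- if (is.matrix(weight)) weight else matrix(weight, n_post, n_pre)
  stopifnot(nrow(w) == n_post, ncol(w) == n_pre)
  if (is.null(mask)) mask <- matrix(TRUE, n_post, n_pre)
  if (any(w < 0)) stop("synaptic weights must be non-negative")
  w[!mask] <- 0
  structure(list(w = w, mask = mask, g = rep(0, n_post), params = params,
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post)),
            class = "synaptic_projection")
}

#' @export
print.synaptic_projection <- function(x, ...) {
  cat(sprintf(
    "<synaptic_projection> %d -> %d, %d synapses, mean weight %.4g, v_rev %g mV\n",
    x$n_pre, x$n_post, sum(x$mask), mean(x$w[x$mask]), x$params$v_rev))
  invisible(x)
}

#' One conductance step
#'
#' Exact exponential decay of the summed postsynaptic conductance (the
#' conductance ODE is linear between spikes, so `exp(-dt/tau)` integrates it
#' exactly) followed by delta-pulse increments `g_bar * W[, j]` for every
#' presynaptic neuron `j` that spiked. Spikes produced at step `t` are, by
#' the engine's convention, delivered here at the start of step `t + 1`.
#'
#' @param proj A [synaptic_projection()].
#' @param presyn_spikes Logical vector of length `n_pre`.
#' @param dt Time step (ms).
#' @return The updated projection.
#' @export
step_conductance <- function(proj, presyn_spikes, dt = 1) {
  stopifnot(length(presyn_spikes) == proj$n_pre, dt > 0)
  if (any(proj$w < 0)) stop("negative synaptic weight: projection invariant violated")
  g <- proj$g * exp(-dt / proj$params$tau_syn)
  for (j in which(presyn_spikes)) {
    g <- g + proj$params$g_bar * proj$w[, j]
  }
  proj$g <- g
  proj
}

#' Summed excitatory conductance delivered by a set of projections
#'
#' @param projections List of [synaptic_projection()] objects sharing a target.
#' @return Per-postsynaptic-neuron conductance sum (nS).
#' @keywords internal
sum_conductance <- function(projections) {
  Reduce(`+`, lapply(projections, `[[`, "g"), 0)
}
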