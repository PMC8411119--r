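# Shared builders for the test suite. Everything is generated in code; no
# stored fixtures.

# A recurrent network expressed for the plain-R reference engine, state-matched
# to a compiled-engine build, with scripted external spikes.
r_engine_recurrent <- function(net, ext, rule = NULL) {
  np <- neuron_params()
  pops <- list(E = neuron_population(net$spec$n_e, np),
               I = neuron_population(net$spec$n_i, np))
  pops$E$v <- net$state$v_e
  pops$I$v <- net$state$v_i
  mk <- function(w, pars, mask = NULL) {
    synaptic_projection(ncol(w), nrow(w), w, pars, mask = mask)
  }
  projs <- list(
    ee = list(pre = "E", post = "E", proj = mk(net$state$w_ee, exc_synapse())),
    ie = list(pre = "E", post = "I", proj = mk(net$state$w_ie, exc_synapse())),
    xe = list(pre = "X", post = "E", proj = mk(net$state$w_xe, exc_synapse())),
    xi = list(pre = "X", post = "I", proj = mk(net$state$w_xi, exc_synapse())),
    ei = list(pre = "I", post = "E",
              proj = mk(net$state$w_ei, inh_synapse(), mask = net$state$m_ei),
              rule = rule))
  list(populations = pops, projections = projs, sources = list(X = ext))
}

# Single-E / single-I toy circuit under iSTDP, driven by a scripted
# excitatory spike train; returns the engine-ready pieces.
toy_ei_circuit <- function(drive, w_in = 3, w_ei0 = 0.1, w_ie = 3,
                           eta = 5e-5, alpha = 0.2) {
  np <- neuron_params()
  pops <- list(E = neuron_population(1, np), I = neuron_population(1, np))
  projs <- list(
    xe = list(pre = "X", post = "E",
              proj = synaptic_projection(ncol(drive), 1, w_in, exc_synapse())),
    xi = list(pre = "X", post = "I",
              proj = synaptic_projection(ncol(drive), 1, w_in, exc_synapse())),
    ie = list(pre = "E", post = "I",
              proj = synaptic_projection(1, 1, w_ie, exc_synapse())),
    ei = list(pre = "I", post = "E",
              proj = synaptic_projection(1, 1, w_ei0, inh_synapse()),
              rule = istdp_rule(1, 1, eta = eta, alpha = alpha)))
  list(populations = pops, projections = projs, sources = list(X = drive))
}

# Independent scalar re-implementation of the same toy circuit, written
# directly from the update equations (the brute-force oracle).
toy_ei_oracle <- function(drive, w_in = 3, w_ei0 = 0.1, w_ie = 3,
                          eta = 5e-5, alpha = 0.2, dt = 1) {
  n <- nrow(drive); nx <- ncol(drive)
  v_e <- -60; v_i <- -60; ref_e <- 0; ref_i <- 0
  g_xe <- 0; g_xi <- 0; g_ie <- 0; g_ei <- 0
  x_pre <- 0; x_post <- 0; w <- w_ei0
  sp_e_prev <- FALSE; sp_i_prev <- FALSE; sp_x_prev <- rep(FALSE, nx)
  spikes_e <- numeric(0)
  fE <- exp(-dt / 5); fI <- exp(-dt / 10); fT <- 1 - dt / 20
  for (s in seq_len(n)) {
    g_xe <- g_xe * fE + w_in * sum(sp_x_prev)
    g_xi <- g_xi * fE + w_in * sum(sp_x_prev)
    g_ie <- g_ie * fE + w_ie * sp_e_prev
    g_ei <- g_ei * fI + w * sp_i_prev
    sp_x <- drive[s, ]
    step1 <- function(v, ref, ge, gi) {
      if (ref > 0) return(list(v = -60, ref = max(ref - dt, 0), sp = FALSE))
      v <- v + (dt / 20) * ((-60 - v) + 1e-3 * 100 * ge * (0 - v) +
                              1e-3 * 100 * gi * (-80 - v))
      v <- min(max(v, -80), 0)
      if (v >= -50) list(v = -60, ref = 2, sp = TRUE) else list(v = v, ref = 0, sp = FALSE)
    }
    se <- step1(v_e, ref_e, g_xe, g_ei); v_e <- se$v; ref_e <- se$ref
    si <- step1(v_i, ref_i, g_xi + g_ie, 0); v_i <- si$v; ref_i <- si$ref
    x_pre <- x_pre * fT + si$sp
    x_post <- x_post * fT + se$sp
    if (si$sp) w <- w + eta * (x_post - alpha)
    if (se$sp) w <- w + eta * x_pre
    w <- max(w, 0)
    if (se$sp) spikes_e <- c(spikes_e, s * dt)
    sp_e_prev <- se$sp; sp_i_prev <- si$sp; sp_x_prev <- sp_x
  }
  list(spikes_e = spikes_e, w = w)
}

# Spearman oracle: average ranks by hand, then the Pearson product-moment
# formula applied to the ranks.
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    s <- sort(v)
    vapply(v, function(x) mean(which(s == x)), 0)
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# per-neuron ISI check against the refractory period
min_isi <- function(spikes, population) {
  ev <- spikes[spikes$population == population, ]
  if (!nrow(ev)) return(Inf)
  min(unlist(lapply(split(ev$time_ms, ev$neuron), function(t) {
    if (length(t) < 2) Inf else min(diff(sort(t)))
  })))
}
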