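#' Spike event log
#'
#' @param population Character vector of population ids.
#' @param neuron Integer neuron indices (1-based within population).
#' @param time_ms Numeric spike times (ms), strictly inside `[0, duration]`.
#' @param duration Total simulated time (ms).
#' @return A `spike_record`: a data.frame with columns `population`, `neuron`,
#'   `time_ms` and a `duration` attribute.
#' @export
spike_record <- function(population = character(), neuron = integer(),
                         time_ms = numeric(), duration = 0) {
  df <- data.frame(population = as.character(population),
                   neuron = as.integer(neuron),
                   time_ms = as.numeric(time_ms),
                   stringsAsFactors = FALSE)
  attr(df, "duration") <- duration
  class(df) <- c("spike_record", "data.frame")
  df
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d events over %g ms (%d populations)\n",
              nrow(x), attr(x, "duration"),
              length(unique(x$population))))
  invisible(x)
}

#' Clocked simulation of an arbitrary small network (reference engine)
#'
#' Plain-R simulation loop used for rule-level experiments and as the
#' reference against which the compiled model engines are checked. Per step:
#' (1) every projection's conductance decays and receives the previous
#' step's presynaptic spikes (one-step delivery delay, no axonal delays);
#' (2) Poisson / scripted sources draw this step's spikes; (3) each
#' population takes one Euler membrane step from its summed conductances and
#' external current; (4) plasticity traces are advanced with this step's
#' conductances and spikes, then spike-triggered weight updates are applied,
#' so a spike sees the current trace.
#'
#' @param populations Named list of [neuron_population()] objects.
#' @param projections Named list; each element a list with fields `pre`
#'   (name of a population or source), `post` (population name), `proj`
#'   (a [synaptic_projection()]), and optionally `rule` (an [idip_rule()],
#'   [hebbian_rule()] or [istdp_rule()] driving this projection's weights)
#'   and `idip_input` (logical, default `TRUE` for excitatory projections
#'   onto a population carrying an IDIP rule: whether this projection's
#'   conductance counts toward the IDIP trace).
#' @param sources Named list of [poisson_source()] objects and/or scripted
#'   spike trains (logical matrices `n_steps x n_units`).
#' @param i_ext Named list mapping population names to a constant current
#'   vector (nA) or a `function(t)` returning one.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param rule_on_at Time (ms) from which plasticity updates apply; traces
#'   run from the start.
#' @param record_v Optional character vector of population names whose
#'   voltage traces to record (one row per step).
#' @return A list with `spikes` (a [spike_record()]), final `populations`,
#'   `projections` (with learned weights), `rules` (final states keyed by
#'   projection name) and, if requested, `v` traces.
#' @export
run_network <- function(populations, projections, sources = list(),
                        i_ext = list(), duration, dt = 1, rule_on_at = 0,
                        record_v = character()) {
  n_steps <- as.integer(round(duration / dt))
  pop_names <- names(populations)
  for (pr in projections) {
    if (!(pr$post %in% pop_names)) {
      stop(sprintf("projection targets unknown population '%s'", pr$post))
    }
    if (!(pr$pre %in% c(pop_names, names(sources)))) {
      stop(sprintf("projection references unknown source '%s'", pr$pre))
    }
  }

  prev_spikes <- lapply(populations, function(p) rep(FALSE, p$size))
  for (s in names(sources)) {
    n <- if (inherits(sources[[s]], "poisson_source")) sources[[s]]$size else ncol(sources[[s]])
    prev_spikes[[s]] <- rep(FALSE, n)
  }

  ev_pop <- list(); ev_id <- list(); ev_t <- list(); n_ev <- 0L
  vtrace <- lapply(populations[record_v], function(p) matrix(NA_real_, n_steps, p$size))

  for (step in seq_len(n_steps)) {
    t_now <- step * dt

    # (1) conductances from previous-step spikes
    for (k in seq_along(projections)) {
      projections[[k]]$proj <- step_conductance(
        projections[[k]]$proj, prev_spikes[[projections[[k]]$pre]], dt)
    }

    # (2) external sources draw this step's spikes
    src_spikes <- list()
    for (s in names(sources)) {
      src_spikes[[s]] <- if (inherits(sources[[s]], "poisson_source")) {
        draw_poisson_spikes(sources[[s]], dt)
      } else {
        as.logical(sources[[s]][step, ])
      }
    }

    # (3) membrane steps
    spikes_now <- list()
    for (p in pop_names) {
      g_e <- 0; g_i <- 0
      for (pr in projections) {
        if (pr$post == p) {
          if (pr$proj$params$v_rev >= populations[[p]]$params$v_rest) {
            g_e <- g_e + pr$proj$g
          } else {
            g_i <- g_i + pr$proj$g
          }
        }
      }
      ie <- i_ext[[p]]
      ie_now <- if (is.null(ie)) 0 else if (is.function(ie)) ie(t_now) else ie
      st <- step_membrane(populations[[p]], g_e, g_i, ie_now, dt, time = t_now)
      populations[[p]] <- st$pop
      spikes_now[[p]] <- st$spiked
      if (p %in% record_v) vtrace[[p]][step, ] <- st$pop$v
      if (any(st$spiked)) {
        n_ev <- n_ev + 1L
        ids <- which(st$spiked)
        ev_pop[[n_ev]] <- rep(p, length(ids)); ev_id[[n_ev]] <- ids
        ev_t[[n_ev]] <- rep(t_now, length(ids))
      }
    }

    # (4) plasticity: traces first, then spike-triggered updates
    learning <- t_now >= rule_on_at
    for (k in seq_along(projections)) {
      pr <- projections[[k]]
      if (is.null(pr$rule)) next
      rule <- pr$rule
      if (inherits(rule, "idip_rule")) {
        inh_pop <- pr$pre  # IDIP lives on the presynaptic (inhibitory) side
        g_in <- 0; g_in_i <- 0
        for (q in projections) {
          if (q$post == inh_pop && !isFALSE(q$idip_input)) {
            if (q$proj$params$v_rev >= populations[[inh_pop]]$params$v_rest) {
              g_in <- g_in + q$proj$g
            } else {
              g_in_i <- g_in_i + q$proj$g
            }
          }
        }
        rule <- idip_update_trace(rule, g_in, dt, g_inh_sum = g_in_i,
                                  v_post = populations[[inh_pop]]$v,
                                  v_rev_exc = populations[[inh_pop]]$params$v_rev_exc,
                                  spikes = spikes_now[[inh_pop]])
        if (learning) {
          upd <- idip_on_spike(rule, spikes_now[[inh_pop]], pr$proj$w,
                               mask = pr$proj$mask, dt = dt)
          projections[[k]]$proj$w <- upd$w
          if (!is.null(upd$dtheta)) {
            th <- populations[[inh_pop]]$theta + upd$dtheta
            vr <- populations[[inh_pop]]$params$v_rest
            populations[[inh_pop]]$theta <- pmin(pmax(th, vr + 1), 0)
          }
        }
      } else if (inherits(rule, "hebbian_rule")) {
        res <- hebbian_step(rule, spikes_now[[pr$pre]], spikes_now[[pr$post]],
                            pr$proj$w, dt, mask = pr$proj$mask)
        rule <- res$state
        if (learning) projections[[k]]$proj$w <- res$w
      } else if (inherits(rule, "istdp_rule")) {
        res <- istdp_step(rule, spikes_now[[pr$pre]], spikes_now[[pr$post]],
                          pr$proj$w, dt, mask = pr$proj$mask)
        rule <- res$state
        if (learning) projections[[k]]$proj$w <- res$w
      }
      projections[[k]]$rule <- rule
    }

    prev_spikes <- c(spikes_now, src_spikes)
  }

  spk <- spike_record(unlist(ev_pop, use.names = FALSE),
                      unlist(ev_id, use.names = FALSE),
                      unlist(ev_t, use.names = FALSE), duration)
  out <- list(spikes = spk, populations = populations,
              projections = projections,
              rules = lapply(projections, `[[`, "rule"))
  if (length(record_v)) out$v <- vtrace
  out
}
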