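#' Specification of the sparse random recurrent network
#'
#' 80 excitatory and 20 inhibitory LIF neurons driven by 100 external Poisson
#' units at 10 Hz. Connectivity uses fixed in-degrees (exact products of the
#' connection probabilities and presynaptic pool sizes, sampled without
#' replacement, no self-connections): each excitatory neuron receives
#' `n_e * p_ee` excitatory and `n_i * p_ei` inhibitory recurrent inputs, each
#' inhibitory neuron `n_e * p_ie` excitatory inputs, and every neuron
#' `n_ex * p_ex` external inputs. Inhibitory-inhibitory synapses are absent
#' by default (`p_ii = 0`) but can be enabled. Recurrent and input weights
#' are lognormal with mean `mu_w` and standard deviation `sigma_wrec` /
#' `sigma_win` (moments of the weight distribution itself); input weights
#' are scaled by `input_gain` to generate sufficient activity, and initial
#' inhibitory weights are `wi_we_ratio` times a draw from the same lognormal
#' family. Only the I->E weights are plastic (IDIP with a multiplicative
#' bound at `idip$w_max`, or the iSTDP baseline).
#'
#' @param n_e,n_i,n_ex Population sizes.
#' @param p_ee,p_ie,p_ei,p_ii,p_ex Connection probabilities (in-degree
#'   fractions).
#' @param mu_w Mean of the lognormal weight distribution.
#' @param sigma_wrec,sigma_win Standard deviations of the recurrent and
#'   input weight distributions.
#' @param input_gain Multiplier on all external input weights.
#' @param wi_we_ratio Initial inhibitory/excitatory weight ratio.
#' @param rate External Poisson rate (Hz).
#' @param idip IDIP parameters: `eta` (1/(ms*nS)), `theta_in` (nS), `tau`
#'   (ms), `w_max`.
#' @param istdp iSTDP parameters: `eta`, `alpha`, `tau` (ms).
#' @param neuron A [neuron_params()] shared by both populations.
#' @return An object of class `recurrent_net_spec`.
#' @export
recurrent_net_spec <- function(n_e = 80, n_i = 20, n_ex = 100,
                               p_ee = 0.1, p_ie = 0.25, p_ei = 0.25,
                               p_ii = 0, p_ex = 0.2,
                               mu_w = 1.0, sigma_wrec = 0.1, sigma_win = 0.1,
                               input_gain = 2.5, wi_we_ratio = 0.1,
                               rate = 10,
                               idip = list(eta = 1e-7, theta_in = 550,
                                           tau = 160, w_max = 5.0),
                               istdp = list(eta = 5e-5, alpha = 0.2, tau = 20),
                               neuron = neuron_params()) {
  structure(as.list(environment()), class = "recurrent_net_spec")
}

#' Draw lognormal weights with given mean and standard deviation
#' @keywords internal
rlnorm_moments <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a fixed in-degree adjacency (internal)
#'
#' Each postsynaptic neuron receives exactly `k` inputs drawn uniformly
#' without replacement from the presynaptic pool, excluding itself when
#' `self` indexes match.
#' @keywords internal
fixed_indegree_mask <- function(n_pre, n_post, k, exclude_self = FALSE) {
  m <- matrix(FALSE, n_post, n_pre)
  if (k == 0) return(m)
  for (j in seq_len(n_post)) {
    pool <- seq_len(n_pre)
    if (exclude_self) pool <- pool[pool != j]
    if (k > length(pool)) {
      stop(sprintf("requested in-degree %d exceeds presynaptic pool %d",
                   k, length(pool)))
    }
    m[j, sample(pool, k)] <- TRUE
  }
  m
}

#' Build the recurrent network from a specification
#'
#' @param spec A [recurrent_net_spec()].
#' @param seed Optional RNG seed; the same seed and spec give an identical
#'   adjacency and weights.
#' @return An object of class `recurrent_net` carrying the full engine state.
#' @export
build_recurrent_net <- function(spec = recurrent_net_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_e <- spec$n_e; n_i <- spec$n_i; n_ex <- spec$n_ex
  k_ee <- round(n_e * spec$p_ee); k_ei <- round(n_i * spec$p_ei)
  k_ie <- round(n_e * spec$p_ie); k_ii <- round(n_i * spec$p_ii)
  k_ex <- round(n_ex * spec$p_ex)

  m_ee <- fixed_indegree_mask(n_e, n_e, k_ee, exclude_self = TRUE)
  m_ie <- fixed_indegree_mask(n_e, n_i, k_ie)
  m_ei <- fixed_indegree_mask(n_i, n_e, k_ei)
  m_ii <- fixed_indegree_mask(n_i, n_i, k_ii, exclude_self = TRUE)
  m_xe <- fixed_indegree_mask(n_ex, n_e, k_ex)
  m_xi <- fixed_indegree_mask(n_ex, n_i, k_ex)

  draw <- function(mask, mean, sd, scale = 1) {
    w <- matrix(0, nrow(mask), ncol(mask))
    w[mask] <- scale * rlnorm_moments(sum(mask), mean, sd)
    w
  }
  w_ee <- draw(m_ee, spec$mu_w, spec$sigma_wrec)
  w_ie <- draw(m_ie, spec$mu_w, spec$sigma_wrec)
  w_ei <- draw(m_ei, spec$mu_w, spec$sigma_wrec, scale = spec$wi_we_ratio)
  w_ii <- draw(m_ii, spec$mu_w, spec$sigma_wrec, scale = spec$wi_we_ratio)
  w_xe <- draw(m_xe, spec$mu_w, spec$sigma_win, scale = spec$input_gain)
  w_xi <- draw(m_xi, spec$mu_w, spec$sigma_win, scale = spec$input_gain)

  nr <- spec$neuron
  params <- list(
    v_rest = nr$v_rest, theta_m = nr$theta_m, r_m = nr$r_m, tau_m = nr$tau_m,
    t_ref = nr$t_ref, g_bar = 1,
    v_rev_exc = nr$v_rev_exc, v_rev_inh = nr$v_rev_inh,
    tau_exc = 5, tau_inh = 10,
    poisson_rate = spec$rate,
    idip_eta = spec$idip$eta, idip_theta_in = spec$idip$theta_in,
    idip_tau = spec$idip$tau, idip_w_max = spec$idip$w_max,
    istdp_eta = spec$istdp$eta, istdp_alpha = spec$istdp$alpha,
    istdp_tau = spec$istdp$tau
  )
  state <- list(
    t = 0,
    v_e = runif(n_e, nr$v_rest, nr$theta_m),
    v_i = runif(n_i, nr$v_rest, nr$theta_m),
    ref_e = rep(0, n_e), ref_i = rep(0, n_i),
    w_ee = w_ee, w_ie = w_ie, w_ei = w_ei, w_xe = w_xe, w_xi = w_xi,
    w_ii = w_ii, m_ei = m_ei,
    g_ee = rep(0, n_e), g_xe = rep(0, n_e), g_ei = rep(0, n_e),
    g_ie = rep(0, n_i), g_xi = rep(0, n_i), g_ii = rep(0, n_i),
    y = rep(0, n_i), x_pre = rep(0, n_i), x_post = rep(0, n_e),
    sp_e = rep(FALSE, n_e), sp_i = rep(FALSE, n_i), sp_x = rep(FALSE, n_ex)
  )
  structure(list(state = state, params = params, spec = spec,
                 masks = list(ee = m_ee, ie = m_ie, ei = m_ei, ii = m_ii,
                              xe = m_xe, xi = m_xi),
                 seed = seed),
            class = "recurrent_net")
}

#' @export
print.recurrent_net <- function(x, ...) {
  cat(sprintf("<recurrent_net> %dE/%dI + %d Poisson units, t = %.1f s, mean I->E weight %.3g\n",
              x$spec$n_e, x$spec$n_i, x$spec$n_ex, x$state$t / 1000,
              mean(x$state$w_ei[x$state$m_ei])))
  invisible(x)
}

.rec_rule_code <- function(rule) {
  switch(rule, none = 0L, idip = 1L, istdp = 2L,
         stop("unknown plasticity rule: ", rule))
}

#' Run the recurrent engine for one stretch of time (internal)
#' @keywords internal
run_recurrent_chunk <- function(net, duration_ms, rule = "idip",
                                rule_on_ms = 15000, record_from_ms = 0,
                                ext_spikes = NULL, dt = 1) {
  res <- sim_recurrent_cpp(net$state, net$params, duration_ms, dt,
                           .rec_rule_code(rule), rule_on_ms, record_from_ms,
                           ext_spikes)
  net$state <- res$state
  spikes <- spike_record(c("E", "I")[res$spike_pop + 1L],
                         res$spike_id, res$spike_t, net$state$t)
  list(net = net, spikes = spikes, y_spike_sum = res$y_spike_sum,
       y_spike_n = res$y_spike_n,
       mean_exc_current = res$mean_exc_current / max(res$current_n, 1),
       mean_inh_current = res$mean_inh_current / max(res$current_n, 1),
       trace = data.frame(t = res$trace_t, w_ei = res$trace_w_ei,
                          y = res$trace_y))
}

#' Mean excitatory population rate of a spike record over a window
#' @keywords internal
window_rate <- function(spikes, population, n_neurons, t_from, t_to) {
  n <- sum(spikes$population == population &
             spikes$time_ms > t_from & spikes$time_ms <= t_to)
  n / n_neurons / ((t_to - t_from) / 1000)
}

#' Stabilization of the recurrent network under inhibitory plasticity
#'
#' Runs the network with the chosen inhibitory rule enabled from
#' `idip_on_at` (the initial window shows the unconstrained, pathologically
#' active regime). The run proceeds in windows of `chunk_ms` and, when
#' `duration` is `NULL`, stops once the windowed mean excitatory rate changes
#' by less than `converge_tol` (relative) between consecutive windows, or at
#' `max_duration`.
#'
#' @param net A [build_recurrent_net()] object.
#' @param rule `"idip"`, `"istdp"` or `"none"`.
#' @param idip_on_at Learning onset (ms).
#' @param duration Fixed run length (ms), or `NULL` to run to convergence.
#' @param chunk_ms Convergence/bookkeeping window (ms).
#' @param converge_tol Relative rate change defining convergence.
#' @param max_duration Hard cap (ms) when running to convergence.
#' @param record_final_ms Length of the final window over which the
#'   spike-triggered IDIP trace average, mean rates and per-neuron mean
#'   membrane currents are reported.
#' @return A list with the updated `net`, `spikes`, `rate_trace` (windowed
#'   mean E and I rates), `trace` (sampled mean I->E weight and IDIP trace),
#'   `converged`, `final_rate` (mean E rate over the final window, Hz),
#'   `y_spike_avg` (+ per-neuron version) and per-neuron mean currents over
#'   the final window.
#' @export
run_stabilization <- function(net, rule = "idip", idip_on_at = 15000,
                              duration = NULL, chunk_ms = 50000,
                              converge_tol = 0.02, max_duration = 900000,
                              record_final_ms = 100000) {
  t_begin <- net$state$t
  total <- if (is.null(duration)) max_duration else duration
  to_convergence <- is.null(duration)
  n_e <- net$spec$n_e; n_i <- net$spec$n_i

  chunks <- list(); rates <- c(); rates_i <- c(); elapsed <- 0
  converged <- FALSE
  while (elapsed < total) {
    this <- min(chunk_ms, total - elapsed)
    ch <- run_recurrent_chunk(net, this, rule = rule, rule_on_ms = idip_on_at,
                              record_from_ms = 0)
    net <- ch$net
    chunks[[length(chunks) + 1L]] <- ch
    r <- window_rate(ch$spikes, "E", n_e, net$state$t - this, net$state$t)
    rates <- c(rates, r)
    rates_i <- c(rates_i, window_rate(ch$spikes, "I", n_i,
                                      net$state$t - this, net$state$t))
    elapsed <- elapsed + this
    if (to_convergence && length(rates) >= 2 &&
        net$state$t - t_begin > idip_on_at - t_begin + 2 * chunk_ms) {
      prev <- rates[length(rates) - 1]
      if (prev > 0 && abs(r - prev) / prev < converge_tol) {
        converged <- TRUE
        break
      }
    }
  }

  spikes <- do.call(rbind, lapply(chunks, `[[`, "spikes"))
  attr(spikes, "duration") <- net$state$t
  class(spikes) <- c("spike_record", "data.frame")

  # final-window statistics, assembled from the trailing chunks
  t_end <- net$state$t
  t_from <- t_end - record_final_ms
  final_rate <- window_rate(spikes, "E", n_e, t_from, t_end)
  n_back <- max(ceiling(record_final_ms / chunk_ms), 1)
  tail_chunks <- chunks[seq.int(max(length(chunks) - n_back + 1, 1), length(chunks))]
  y_sum <- Reduce(`+`, lapply(tail_chunks, `[[`, "y_spike_sum"))
  y_n <- Reduce(`+`, lapply(tail_chunks, `[[`, "y_spike_n"))
  cur_e <- rowMeans(do.call(cbind, lapply(tail_chunks, `[[`, "mean_exc_current")))
  cur_i <- rowMeans(do.call(cbind, lapply(tail_chunks, `[[`, "mean_inh_current")))

  list(net = net, spikes = spikes,
       rate_trace = data.frame(
         t = t_begin + seq_along(rates) * chunk_ms,
         rate_e = rates, rate_i = rates_i),
       trace = do.call(rbind, lapply(chunks, `[[`, "trace")),
       converged = converged, final_rate = final_rate,
       y_spike_avg = sum(y_sum) / max(sum(y_n), 1),
       y_spike_avg_by_neuron = y_sum / pmax(y_n, 1),
       y_spike_n = y_n,
       mean_exc_current = cur_e, mean_inh_current = cur_i)
}

#' Sweep of the IDIP target input against inhibitory connectivity
#'
#' Rebuilds the network for every combination of `theta_values` (IDIP target
#' input, nS) and `p_ei_values` (I->E connectivity; in-degrees are re-derived
#' per cell) across `n_seeds` seeds, stabilizes each, and reports the
#' converged mean excitatory rate.
#'
#' @param theta_values IDIP target inputs (nS).
#' @param p_ei_values Inhibitory-to-excitatory connection probabilities.
#' @param n_seeds Seeds per grid cell.
#' @param base_seed First seed.
#' @param spec Base [recurrent_net_spec()].
#' @param duration Run length per simulation (ms).
#' @param record_final_ms Averaging window for the converged rate (ms).
#' @return A data.frame with columns `theta_in`, `p_ei`, `mean_rate_hz`,
#'   `std_rate_hz`, `n_seeds`.
#' @export
sweep_theta_connectivity <- function(theta_values, p_ei_values, n_seeds = 20,
                                     base_seed = 1, spec = recurrent_net_spec(),
                                     duration = 200000,
                                     record_final_ms = 50000) {
  grid <- expand.grid(theta_in = theta_values, p_ei = p_ei_values)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- spec
    sp$idip$theta_in <- grid$theta_in[i]
    sp$p_ei <- grid$p_ei[i]
    rr <- vapply(seq_len(n_seeds), function(k) {
      set.seed(base_seed + k - 1)
      net <- build_recurrent_net(sp)
      run_stabilization(net, duration = duration,
                        record_final_ms = record_final_ms)$final_rate
    }, 0)
    data.frame(theta_in = grid$theta_in[i], p_ei = grid$p_ei[i],
               mean_rate_hz = mean(rr), std_rate_hz = sd(rr),
               n_seeds = n_seeds)
  })
  do.call(rbind, out)
}

#' Increased external drive to a subset of excitatory neurons
#'
#' Scales the external input weights of a subset of excitatory neurons by
#' `input_gain` from the start of the run, then stabilizes under IDIP. Under
#' the network-centered rule the boosted subset sustains a higher rate while
#' the whole-network mean is maintained.
#'
#' @param net A freshly built [build_recurrent_net()].
#' @param subset_fraction Fraction of excitatory neurons boosted.
#' @param input_gain Multiplier on the subset's external weights (1.5 =
#'   +50%).
#' @param rule Inhibitory plasticity rule.
#' @param duration Run length (ms).
#' @param record_final_ms Averaging window (ms).
#' @param bin_ms Width of the reported rate-trace bins (ms).
#' @return A list with `subset` (indices), per-group rate traces
#'   (`rate_trace`), and final-window mean rates `boosted`, `rest`,
#'   `network`.
#' @export
run_subset_drive <- function(net, subset_fraction = 12 / 80, input_gain = 1.5,
                             rule = "idip", duration = 300000,
                             record_final_ms = 50000, bin_ms = 5000) {
  n_e <- net$spec$n_e
  subset <- seq_len(max(round(subset_fraction * n_e), 1))
  net$state$w_xe[subset, ] <- net$state$w_xe[subset, ] * input_gain
  st <- run_stabilization(net, rule = rule, duration = duration,
                          record_final_ms = record_final_ms)
  e <- st$spikes[st$spikes$population == "E", ]
  tr <- bin_rates(st$spikes, bin_ms, population = "E", n_neurons = n_e)
  in_sub <- seq_len(n_e) %in% subset
  t_end <- st$net$state$t; t_from <- t_end - record_final_ms
  rate_of <- function(idx) {
    sum(e$neuron %in% which(idx) & e$time_ms > t_from) /
      sum(idx) / (record_final_ms / 1000)
  }
  list(subset = subset, stabilization = st,
       rate_trace = data.frame(
         t = tr$mid,
         boosted = colMeans(tr$rate[in_sub, , drop = FALSE]),
         rest = colMeans(tr$rate[!in_sub, , drop = FALSE])),
       boosted = rate_of(in_sub), rest = rate_of(!in_sub),
       network = window_rate(st$spikes, "E", n_e, t_from, t_end))
}

#' Firing-rate rank preservation report
#'
#' Splits the excitatory activity into `bin_ms` bins (the first bin is the
#' activity before any inhibitory plasticity when binning starts at 0) and
#' computes the Spearman rank correlation between the per-neuron mean rates
#' in the first bin and every bin.
#'
#' @param spikes A [spike_record()].
#' @param n_neurons Number of excitatory neurons.
#' @param bin_ms Bin width (ms); 15 s by default.
#' @param population Population id to use.
#' @return An object of class `rank_report`: data.frame with `bin_start`,
#'   `bin_end` and `rho` (`NA` where a bin has no variance across neurons).
#' @export
compute_rank_report <- function(spikes, n_neurons, bin_ms = 15000,
                                population = "E") {
  dur <- attr(spikes, "duration")
  if (is.null(dur) || dur < 2 * bin_ms) stop("need at least two full bins")
  tr <- bin_rates(spikes, bin_ms, population = population,
                  n_neurons = n_neurons)
  first <- tr$rate[, 1]
  rho <- apply(tr$rate, 2, function(r) spearman_rank(first, r))
  structure(data.frame(bin_start = tr$breaks[-length(tr$breaks)],
                       bin_end = tr$breaks[-1], rho = rho),
            class = c("rank_report", "data.frame"))
}

#' Associative memory protocol specification
#'
#' @param stabilization_end Time of memory encoding (ms).
#' @param ensemble_size Number of excitatory neurons in the memory ensemble.
#' @param potentiation_factor Multiplier on the recurrent synapses within
#'   the ensemble at encoding.
#' @param recall_time Time of the recall cue (ms).
#' @param cue_size Number of ensemble neurons cued.
#' @param cue_gain Multiplier on the cued neurons' external input weights.
#' @param recall_duration Time simulated after the cue (ms).
#' @return An object of class `memory_protocol_spec`.
#' @export
memory_protocol_spec <- function(stabilization_end = 600000,
                                 ensemble_size = 12, potentiation_factor = 5,
                                 recall_time = 1200000, cue_size = 2,
                                 cue_gain = 1.5, recall_duration = 300000) {
  stopifnot(stabilization_end < recall_time, cue_size <= ensemble_size)
  structure(as.list(environment()), class = "memory_protocol_spec")
}

#' Associative memory encoding and recall
#'
#' Stabilize the network under the chosen inhibitory rule; at
#' `stabilization_end`, multiply the existing recurrent excitatory synapses
#' within a randomly selected ensemble by `potentiation_factor`; let the
#' network re-converge; at `recall_time`, increase the external input weights
#' of `cue_size` ensemble neurons by `cue_gain`. Mean rates of the ensemble
#' and the rest are probed over 50-s windows just before/after encoding and
#' just before/after recall.
#'
#' @param net A freshly built [build_recurrent_net()].
#' @param protocol A [memory_protocol_spec()].
#' @param rule `"idip"` or `"istdp"`.
#' @param probe_ms Probe window length (ms).
#' @return A list with `ensemble`, `cue` indices, `probes` (data.frame:
#'   phase, ensemble / noncue-ensemble / rest mean rates), per-neuron rates
#'   at each probe, and the full `spikes`.
#' @export
run_memory_task <- function(net, protocol = memory_protocol_spec(),
                            rule = "idip", probe_ms = 50000) {
  n_e <- net$spec$n_e
  ensemble <- sort(sample(seq_len(n_e), protocol$ensemble_size))
  cue <- sort(sample(ensemble, protocol$cue_size))

  st1 <- run_stabilization(net, rule = rule,
                           duration = protocol$stabilization_end)
  net <- st1$net
  net$state$w_ee[ensemble, ensemble] <-
    net$state$w_ee[ensemble, ensemble] * protocol$potentiation_factor
  st2 <- run_stabilization(net, rule = rule, idip_on_at = 0,
                           duration = protocol$recall_time -
                             protocol$stabilization_end)
  net <- st2$net
  net$state$w_xe[cue, ] <- net$state$w_xe[cue, ] * protocol$cue_gain
  st3 <- run_stabilization(net, rule = rule, idip_on_at = 0,
                           duration = protocol$recall_duration)
  net <- st3$net

  spikes <- rbind(st1$spikes, st2$spikes, st3$spikes)
  attr(spikes, "duration") <- net$state$t
  class(spikes) <- c("spike_record", "data.frame")

  e <- spikes[spikes$population == "E", ]
  probe_rate <- function(t_from, t_to) {
    cnt <- table(factor(e$neuron[e$time_ms > t_from & e$time_ms <= t_to],
                        levels = seq_len(n_e)))
    as.numeric(cnt) / ((t_to - t_from) / 1000)
  }
  windows <- list(
    pre_encoding = c(protocol$stabilization_end - probe_ms,
                     protocol$stabilization_end),
    post_encoding = c(protocol$stabilization_end,
                      protocol$stabilization_end + probe_ms),
    pre_recall = c(protocol$recall_time - probe_ms, protocol$recall_time),
    post_recall = c(protocol$recall_time, protocol$recall_time + probe_ms))
  rates <- lapply(windows, function(w) probe_rate(w[1], w[2]))
  in_ens <- seq_len(n_e) %in% ensemble
  noncue <- in_ens & !(seq_len(n_e) %in% cue)
  probes <- data.frame(
    phase = names(windows),
    ensemble = vapply(rates, function(r) mean(r[in_ens]), 0),
    noncue_ensemble = vapply(rates, function(r) mean(r[noncue]), 0),
    rest = vapply(rates, function(r) mean(r[!in_ens]), 0),
    row.names = NULL)
  list(ensemble = ensemble, cue = cue, probes = probes,
       rates = rates, spikes = spikes, net = net)
}
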