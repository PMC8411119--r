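#' Geometry of the 1D annular track
#'
#' The simulated animal moves at constant speed on an annulus tiled with
#' `n_fields` equally spaced Gaussian place fields; it takes 3 s to move
#' between adjacent field centers, so one lap lasts `n_fields * 3` s. The
#' printed tuning width (6.54 a.u.) is anchored here to a circumference of
#' 100 a.u. (10 a.u. between centers), which gives overlapping tiled fields;
#' both are configurable.
#'
#' @param n_fields Number of place fields.
#' @param circumference Track length (a.u.).
#' @param sigma_pc Gaussian tuning width (a.u.).
#' @param a_c Place current amplitude (nA; 0.2 nA = 200 pA).
#' @param secs_between_fields Travel time between adjacent centers (s).
#' @return An object of class `track_geometry` with derived `field_centers`,
#'   `speed` (a.u./ms) and `lap_ms`.
#' @export
track_geometry <- function(n_fields = 10, circumference = 100,
                           sigma_pc = 6.54, a_c = 0.2,
                           secs_between_fields = 3) {
  spacing <- circumference / n_fields
  structure(list(
    n_fields = as.integer(n_fields), circumference = circumference,
    sigma_pc = sigma_pc, a_c = a_c,
    field_centers = spacing * (seq_len(n_fields) - 1),
    spacing = spacing,
    speed = spacing / (secs_between_fields * 1000),
    lap_ms = n_fields * secs_between_fields * 1000
  ), class = "track_geometry")
}

#' Circular distance on the annulus
#' @keywords internal
circular_distance <- function(p, p0, circumference) {
  d <- abs(p - p0) %% circumference
  pmin(d, circumference - d)
}

#' Place-tuned external current
#'
#' Gaussian tuning `T(p) = exp(-d^2 / (2 sigma_pc^2))` of the circular
#' distance `d` between the animal's position and a field center, scaled by
#' the current amplitude: `I(p) = A_c * T(p)`.
#'
#' @param track A [track_geometry()].
#' @param position Position on the track (a.u.), wrapped modulo the
#'   circumference.
#' @param field_index Which field center to use.
#' @return Current in nA.
#' @export
place_current <- function(track, position, field_index = 1) {
  d <- circular_distance(position %% track$circumference,
                         track$field_centers[field_index],
                         track$circumference)
  track$a_c * exp(-d^2 / (2 * track$sigma_pc^2))
}

#' Build the hippocampal CA3 -> CA1 network
#'
#' `n_ca3` CA3 cells each receive current from one unique place field. The
#' `n_e` CA1 excitatory cells are divided into `n_groups` equal groups, each
#' tuned to one CA3 cell's field: every CA1 cell receives the same Gaussian
#' place current with a per-neuron amplitude offset `s` drawn once as
#' `n_e / n_groups` values from Normal(0, 0.05) and independently shuffled
#' within each group (the same offset multiset everywhere). CA3 projects to
#' every CA1 excitatory cell with uniform initial weight
#' `theta_homeo / n_ca3` (the weight sum starts exactly at the homeostatic
#' target); this projection is plastic under the Hebbian + homeostatic rule.
#' Excitatory and inhibitory CA1 cells are fully and bidirectionally
#' connected: E->I fixed at `w_ie`, I->E initialized at `w_ei` and plastic
#' under additive IDIP (clipped below at zero, no upper bound).
#'
#' @param seed Optional RNG seed (controls the offset sampling/shuffles).
#' @param n_ca3,n_e,n_i,n_groups Population sizes and grouping.
#' @param track A [track_geometry()].
#' @param w_ie Fixed E->I weight.
#' @param w_ei Initial I->E weight.
#' @param offset_sd Standard deviation of the tuning amplitude offsets.
#' @param i_ex_e,i_ex_i Uniform background currents (nA) to CA1 excitatory
#'   and inhibitory cells. The inhibitory default (0.5 nA, i.e. 50 mV of
#'   tonic drive at R = 100 megaohm) makes the inhibitory population fire
#'   tonically and asynchronously; the excitatory feedback then modulates
#'   this baseline and IDIP sets the inhibitory weight scale. Without tonic
#'   drive the fully connected inhibitory population fires only in
#'   synchronized volleys and the balanced state is unreachable.
#' @param idip Parameters of the IDIP rule: list with `eta`, `theta_in`,
#'   `tau`.
#' @param hebb Parameters of the Hebbian rule: list with `eta_hebb`,
#'   `eta_homeo`, `theta_homeo`, `w_max`, `tau`.
#' @param neuron A [neuron_params()] shared by all three populations.
#' @return An object of class `hippocampal_net`.
#' @export
build_hippocampal_net <- function(seed = NULL, n_ca3 = 10, n_e = 100,
                                  n_i = 20, n_groups = 10,
                                  track = track_geometry(),
                                  w_ie = 2.0, w_ei = 1e-3,
                                  offset_sd = 0.05,
                                  i_ex_e = 0.01, i_ex_i = 0.5,
                                  idip = list(eta = 1e-5, theta_in = 200, tau = 160),
                                  hebb = list(eta_hebb = 1e-3, eta_homeo = 1e-4,
                                              theta_homeo = 5.2, w_max = 1.5,
                                              tau = 20),
                                  neuron = neuron_params()) {
  stopifnot(n_e %% n_groups == 0, track$n_fields >= n_groups)
  if (!is.null(seed)) set.seed(seed)
  per_group <- n_e / n_groups
  group <- rep(seq_len(n_groups), each = per_group)

  s_base <- rnorm(per_group, 0, offset_sd)
  s_e <- unlist(lapply(seq_len(n_groups), function(g) sample(s_base)))

  params <- list(
    v_rest = neuron$v_rest, theta_m = neuron$theta_m, r_m = neuron$r_m,
    tau_m = neuron$tau_m, t_ref = neuron$t_ref,
    g_bar = 1, v_rev_exc = neuron$v_rev_exc, v_rev_inh = neuron$v_rev_inh,
    tau_exc = 5, tau_inh = 10,
    i_ex_e = i_ex_e, i_ex_i = i_ex_i,
    circumference = track$circumference, sigma_pc = track$sigma_pc,
    a_c = track$a_c, speed = track$speed,
    centers_ca3 = track$field_centers[seq_len(n_ca3)],
    centers_e = track$field_centers[group],
    offsets_e = s_e,
    eta_hebb = hebb$eta_hebb, eta_homeo = hebb$eta_homeo,
    theta_homeo = hebb$theta_homeo, hebb_w_max = hebb$w_max,
    tau_hebb = hebb$tau,
    idip_eta = idip$eta, idip_theta_in = idip$theta_in, idip_tau = idip$tau
  )

  # initial membrane potentials are drawn uniformly between rest and
  # threshold: the fully connected inhibitory population receives identical
  # input, so equal initial conditions would lock it into synchronized
  # volleys of pulsed inhibition instead of the smooth lateral inhibition
  # the balanced state needs
  state <- list(
    t = 0,
    v_ca3 = runif(n_ca3, neuron$v_rest, neuron$theta_m),
    v_e = runif(n_e, neuron$v_rest, neuron$theta_m),
    v_i = runif(n_i, neuron$v_rest, neuron$theta_m),
    ref_ca3 = rep(0, n_ca3), ref_e = rep(0, n_e), ref_i = rep(0, n_i),
    w_ff = matrix(hebb$theta_homeo / n_ca3, n_e, n_ca3),
    w_ie = matrix(w_ie, n_i, n_e),
    w_ei = matrix(w_ei, n_e, n_i),
    g_ff = rep(0, n_e), g_ei = rep(0, n_e), g_ie = rep(0, n_i),
    y = rep(0, n_i), x_ca3 = rep(0, n_ca3), x_e = rep(0, n_e),
    sp_ca3 = rep(FALSE, n_ca3), sp_e = rep(FALSE, n_e), sp_i = rep(FALSE, n_i)
  )

  structure(list(state = state, params = params, track = track,
                 group = group, n_ca3 = as.integer(n_ca3),
                 n_e = as.integer(n_e), n_i = as.integer(n_i),
                 labels = NULL, seed = seed),
            class = "hippocampal_net")
}

#' @export
print.hippocampal_net <- function(x, ...) {
  cat(sprintf("<hippocampal_net> CA3 %d -> CA1 %dE/%dI, t = %.1f s%s\n",
              x$n_ca3, x$n_e, x$n_i, x$state$t / 1000,
              if (is.null(x$labels)) "" else
                sprintf(", %d active / %d silent", sum(x$labels == "active"),
                        sum(x$labels == "silent"))))
  invisible(x)
}

.hippo_pop_names <- c("CA3", "CA1E", "CA1I")

#' Run the hippocampal engine for a number of laps (internal)
#' @keywords internal
run_hippo_laps <- function(net, n_laps, hebb_on = TRUE, idip_on = TRUE,
                           silence = NULL, record_y_from = Inf, dt = 1) {
  mask <- if (is.null(silence)) logical(0) else as.logical(silence)
  res <- sim_hippocampus_cpp(net$state, net$params,
                             n_laps * net$track$lap_ms, dt,
                             hebb_on, idip_on, mask, record_y_from)
  net$state <- res$state
  spikes <- spike_record(.hippo_pop_names[res$spike_pop + 1L],
                         res$spike_id, res$spike_t, net$state$t)
  list(net = net, spikes = spikes,
       y_spike_sum = res$y_spike_sum, y_spike_n = res$y_spike_n,
       trace = data.frame(t = res$trace_t, w_ei = res$trace_w_ei,
                          y = res$trace_y))
}

#' Per-lap place-map rates from a spike record
#'
#' Builds the lap-resolved report used by all hippocampal protocols: for each
#' CA1 excitatory neuron and lap, the overall lap rate and the in-field rate
#' (spikes emitted while the animal is within half a field spacing of the
#' neuron's field center, divided by the time spent there).
#'
#' @param spikes A [spike_record()] containing `CA1E` events.
#' @param net The [build_hippocampal_net()] object (for geometry and groups).
#' @param lap_offset Lap numbering offset of the first lap in `spikes`.
#' @param t_start Absolute time (ms) at which the first lap begins.
#' @param n_laps Number of laps covered by the record.
#' @return An object of class `place_map_report`: list with matrices
#'   `rate` and `infield_rate` (`n_e x n_laps`, Hz), `labels` (if the net
#'   carries them) and bookkeeping fields.
#' @export
place_map_report <- function(spikes, net, t_start, n_laps, lap_offset = 0) {
  lap_ms <- net$track$lap_ms
  e <- spikes[spikes$population == "CA1E", , drop = FALSE]
  lap_of <- floor((e$time_ms - t_start - 1e-9) / lap_ms) + 1L
  keep <- lap_of >= 1L & lap_of <= n_laps
  e <- e[keep, , drop = FALSE]; lap_of <- lap_of[keep]

  rate <- matrix(0, net$n_e, n_laps)
  infield <- matrix(0, net$n_e, n_laps)
  if (nrow(e)) {
    cnt <- table(factor(e$neuron, levels = seq_len(net$n_e)),
                 factor(lap_of, levels = seq_len(n_laps)))
    rate <- matrix(as.numeric(cnt), net$n_e, n_laps) / (lap_ms / 1000)

    pos <- (net$params$speed * e$time_ms) %% net$track$circumference
    d <- circular_distance(pos, net$params$centers_e[e$neuron],
                           net$track$circumference)
    inf <- d <= net$track$spacing / 2
    if (any(inf)) {
      cnt_in <- table(factor(e$neuron[inf], levels = seq_len(net$n_e)),
                      factor(lap_of[inf], levels = seq_len(n_laps)))
      infield_s <- lap_ms / 1000 / net$track$n_fields  # dwell time per lap
      infield <- matrix(as.numeric(cnt_in), net$n_e, n_laps) / infield_s
    }
  }
  structure(list(rate = rate, infield_rate = infield,
                 labels = net$labels, group = net$group,
                 n_laps = n_laps, lap_offset = lap_offset,
                 lap_ms = lap_ms),
            class = "place_map_report")
}

#' @export
print.place_map_report <- function(x, ...) {
  cat(sprintf("<place_map_report> %d neurons x %d laps, mean rate %.3g Hz\n",
              nrow(x$rate), x$n_laps, mean(x$rate)))
  invisible(x)
}

#' Label place cells as active or silent
#'
#' Default rule: a cell is active on a given lap if its in-field rate exceeds
#' `threshold_frac` of the population's maximum in-field rate on that lap.
#' The rule is scale free, so it is robust to overall rate changes.
#'
#' @param report A [place_map_report()].
#' @param threshold_frac Fraction of the population peak (default 0.1).
#' @param lap Which lap to classify on (default: the last).
#' @return Character vector of `"active"` / `"silent"` labels.
#' @export
classify_place_cells <- function(report, threshold_frac = 0.1, lap = NULL) {
  if (is.null(lap)) lap <- report$n_laps
  r <- report$infield_rate[, lap]
  if (all(r == 0)) {
    warning("no spikes on the classification lap: labeling all cells silent")
    return(rep("silent", length(r)))
  }
  ifelse(r > threshold_frac * max(r), "active", "silent")
}

#' Exploration phase on the annular track
#'
#' Simulates `n_laps` laps at constant speed. During the first
#' `plasticity_on_after_lap` lap(s) all weights are frozen (the IDIP input
#' trace still runs); from the next lap on, the CA3->CA1 Hebbian rule and the
#' I->E IDIP rule are both active. Returns the lap-resolved place-map report
#' with active/silent labels assigned on the final lap, and the trained
#' network for use by the silencing and consolidation protocols.
#'
#' @param net A freshly built [build_hippocampal_net()].
#' @param n_laps Number of laps (the full protocol uses 100; shorter
#'   explorations converge much earlier and are used throughout the tests).
#' @param plasticity_on_after_lap Laps to run before learning starts.
#' @param record_y_laps Final laps over which the spike-triggered IDIP trace
#'   statistics are accumulated.
#' @return A list with `net` (trained, labels attached), `report`,
#'   `spikes`, `trace` (sampled mean I->E weight and mean IDIP trace) and
#'   `y_spike_avg` (spike-triggered average of the IDIP trace over the
#'   recorded laps, pooled across inhibitory neurons).
#' @export
run_exploration <- function(net, n_laps = 100, plasticity_on_after_lap = 1,
                            record_y_laps = 5) {
  stopifnot(n_laps > plasticity_on_after_lap)
  t_start <- net$state$t
  pre <- run_hippo_laps(net, plasticity_on_after_lap,
                        hebb_on = FALSE, idip_on = FALSE)
  record_from <- t_start + (n_laps - record_y_laps) * net$track$lap_ms
  post <- run_hippo_laps(pre$net, n_laps - plasticity_on_after_lap,
                         hebb_on = TRUE, idip_on = TRUE,
                         record_y_from = record_from)
  net <- post$net
  spikes <- rbind(pre$spikes, post$spikes)
  attr(spikes, "duration") <- net$state$t
  class(spikes) <- c("spike_record", "data.frame")

  report <- place_map_report(spikes, net, t_start, n_laps)
  net$labels <- classify_place_cells(report)
  report$labels <- net$labels
  y_avg <- sum(post$y_spike_sum) / max(sum(post$y_spike_n), 1)
  list(net = net, report = report, spikes = spikes,
       trace = rbind(pre$trace, post$trace),
       y_spike_avg = y_avg,
       y_spike_avg_by_neuron = post$y_spike_sum / pmax(post$y_spike_n, 1))
}

#' Mean firing rate of a labeled place map over a lap
#' @keywords internal
map_rate <- function(report, lap, labels, map = c("active", "silent")) {
  map <- match.arg(map)
  mean(report$rate[labels == map, lap])
}

#' Acute silencing of the active place map
#'
#' One baseline lap (OFF), one lap with every labeled active cell clamped at
#' rest (ON; idealized optogenetic silencing — clamped cells cannot spike,
#' their conductances keep decaying), and one release lap. With
#' `with_idip = FALSE` the I->E weights are frozen from silencing onset to
#' the end of the silencing lap; Hebbian plasticity stays on throughout.
#'
#' @param net A trained network with labels (from [run_exploration()]).
#' @param with_idip Keep IDIP active during the silencing lap?
#' @param release_laps Laps simulated after release.
#' @return A list with the 3-phase `report`, the map summary `rates`
#'   (original and alternative map member-mean rates per phase, plus the
#'   population mean), `spikes` and the updated `net`.
#' @export
run_silencing <- function(net, with_idip = TRUE, release_laps = 1) {
  if (is.null(net$labels)) stop("no active cells labeled: run exploration first")
  if (!any(net$labels == "active")) stop("protocol error: no active cells to silence")
  labels <- net$labels
  t_start <- net$state$t

  off <- run_hippo_laps(net, 1, hebb_on = TRUE, idip_on = TRUE)
  on <- run_hippo_laps(off$net, 1, hebb_on = TRUE, idip_on = with_idip,
                       silence = labels == "active")
  post <- run_hippo_laps(on$net, release_laps, hebb_on = TRUE, idip_on = TRUE)

  net <- post$net
  spikes <- rbind(off$spikes, on$spikes, post$spikes)
  attr(spikes, "duration") <- net$state$t
  class(spikes) <- c("spike_record", "data.frame")
  n_laps <- 2 + release_laps
  report <- place_map_report(spikes, net, t_start, n_laps)

  phases <- c("off", "on", rep("release", release_laps))
  rates <- data.frame(
    phase = phases, lap = seq_len(n_laps),
    original = vapply(seq_len(n_laps), map_rate, 0, report = report,
                      labels = labels, map = "active"),
    alternative = vapply(seq_len(n_laps), map_rate, 0, report = report,
                         labels = labels, map = "silent"),
    population = colMeans(report$rate))
  list(report = report, rates = rates, spikes = spikes, net = net)
}

#' Repeated-silencing consolidation protocol
#'
#' The established (active) map is silenced for `silencing_laps` consecutive
#' laps, then released for `test_laps` lap(s); this is repeated `n_trials`
#' times. Trial 0 is a plain lap run immediately after exploration. Hebbian
#' and IDIP plasticity stay on throughout (set `hebbian_on = FALSE` to freeze
#' the CA3->CA1 weights and ablate the consolidation mechanism).
#'
#' @param net A trained, labeled network.
#' @param n_trials Number of silencing trials.
#' @param silencing_laps Silenced laps per trial.
#' @param test_laps Test laps per trial.
#' @param hebbian_on Keep CA3->CA1 plasticity active?
#' @return A list with `test_rates` (data.frame: trial, original and
#'   alternative map member-mean test-lap rates) and the final `net`.
#' @export
run_consolidation <- function(net, n_trials = 10, silencing_laps = 4,
                              test_laps = 1, hebbian_on = TRUE) {
  if (is.null(net$labels)) stop("no active cells labeled: run exploration first")
  labels <- net$labels
  res <- data.frame(trial = 0:n_trials, original = NA_real_,
                    alternative = NA_real_)

  measure_lap <- function(net) {
    t0 <- net$state$t
    lap <- run_hippo_laps(net, test_laps, hebb_on = hebbian_on, idip_on = TRUE)
    rep <- place_map_report(lap$spikes, lap$net, t0, test_laps)
    list(net = lap$net,
         original = map_rate(rep, 1, labels, "active"),
         alternative = map_rate(rep, 1, labels, "silent"))
  }

  m <- measure_lap(net)  # trial 0: activity just after exploration
  res$original[1] <- m$original; res$alternative[1] <- m$alternative
  net <- m$net
  for (trial in seq_len(n_trials)) {
    sil <- run_hippo_laps(net, silencing_laps, hebb_on = hebbian_on,
                          idip_on = TRUE, silence = labels == "active")
    m <- measure_lap(sil$net)
    res$original[trial + 1] <- m$original
    res$alternative[trial + 1] <- m$alternative
    net <- m$net
  }
  list(test_rates = res, net = net)
}
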