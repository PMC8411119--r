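# CA3 -> CA1 place-cell network: geometry, build, exploration and
# classification. Protocol-level homeostasis claims live in test-acceptance.R;
# here a short exploration (12 laps) exercises the mechanics.

hippo_short <- local({
  env <- new.env()
  function() {
    if (is.null(env$ex)) {
      net <- build_hippocampal_net(seed = 3)
      env$net0 <- net
      env$ex <- run_exploration(net, n_laps = 12, record_y_laps = 3)
    }
    list(net0 = env$net0, ex = env$ex)
  }
})

test_that("place current follows the Gaussian tuning with circular distance", {
  tr <- track_geometry()
  p0 <- tr$field_centers[4]
  expect_equal(place_current(tr, p0, 4), 0.2)                     # A_c at center
  expect_equal(place_current(tr, p0 + tr$sigma_pc, 4), 0.2 * exp(-0.5),
               tolerance = 1e-12)                                 # ~121.31 pA
  # wrapped distance: positions 2 and 98 are 4 a.u. apart around the annulus
  expect_equal(place_current(tr, 98, 1) , place_current(tr, 2, 1))
  # diametrically opposite: wrapped distance = circumference / 2, positive
  opp <- place_current(tr, p0 + 50, 4)
  expect_gt(opp, 0)
  expect_equal(opp, 0.2 * exp(-50^2 / (2 * tr$sigma_pc^2)))
})

test_that("the built network matches the wiring and initialization contract", {
  net <- build_hippocampal_net(seed = 1)
  expect_equal(dim(net$state$w_ff), c(100, 10))
  expect_true(all(net$state$w_ff == 5.2 / 10))      # sum = theta_homeo
  expect_true(all(net$state$w_ie == 2.0))           # full E->I at W_IE
  expect_true(all(net$state$w_ei == 1e-3))          # full I->E, low initial
  expect_equal(dim(net$state$w_ie), c(20, 100))     # every I gets all 100 E
  expect_equal(dim(net$state$w_ei), c(100, 20))     # every E gets all 20 I
  # amplitude offsets: the same multiset in every group, shuffled per group
  off <- split(net$params$offsets_e, net$group)
  base <- sort(off[[1]])
  for (g in seq_along(off)) expect_equal(sort(off[[g]]), base)
  # reproducible builds
  net2 <- build_hippocampal_net(seed = 1)
  expect_identical(net$params$offsets_e, net2$params$offsets_e)
  expect_identical(net$state$v_e, net2$state$v_e)
})

test_that("every place cell is active within its field on the first lap", {
  h <- hippo_short()
  expect_equal(sum(h$ex$report$infield_rate[, 1] > 0), 100)
})

test_that("active and silent cells emerge per group, ordered by tuning offset", {
  h <- hippo_short()
  labels <- h$ex$net$labels
  expect_setequal(unique(labels), c("active", "silent"))
  per_group <- tapply(labels == "active", h$net0$group, sum)
  expect_true(all(per_group >= 1 & per_group <= 9))  # both kinds in each group
  s <- h$net0$params$offsets_e
  expect_gt(mean(s[labels == "active"]), mean(s[labels == "silent"]))
})

test_that("with plasticity off the lap dynamics are exactly conserved", {
  net <- build_hippocampal_net(seed = 8)
  w0 <- net$state$w_ff; wei0 <- net$state$w_ei
  run <- idipnet:::run_hippo_laps(net, 2, hebb_on = FALSE, idip_on = FALSE)
  expect_identical(run$net$state$w_ff, w0)
  expect_identical(run$net$state$w_ei, wei0)
  # the two laps traverse identical positions: identical per-lap rates
  rep2 <- place_map_report(run$spikes, run$net, 0, 2)
  expect_equal(rep2$rate[, 1], rep2$rate[, 2], tolerance = 0.05)
})

test_that("inhibitory cells are spatially flat relative to place cells", {
  h <- hippo_short()
  sp <- h$ex$spikes
  last5 <- sp[sp$time_ms > max(sp$time_ms) - 5 * 30000, ]
  pos_bin <- function(pop) {
    ev <- last5[last5$population == pop, ]
    pos <- (h$ex$net$params$speed * ev$time_ms) %% 100
    tabulate(findInterval(pos, seq(0, 100, by = 10),
                          rightmost.closed = TRUE), 10)
  }
  depth <- function(x) (max(x) - min(x)) / (max(x) + min(x))
  e_depth <- depth(pos_bin("CA1E"))  # population rate is flat-ish for E too;
  i_depth <- depth(pos_bin("CA1I"))  # compare single-cell modulation instead
  ev <- last5[last5$population == "CA1E", ]
  cell <- as.integer(names(which.max(table(ev$neuron))))
  pos_cell <- (h$ex$net$params$speed * ev$time_ms[ev$neuron == cell]) %% 100
  cell_depth <- depth(tabulate(findInterval(pos_cell, seq(0, 100, by = 10),
                                            rightmost.closed = TRUE) , 10) + 0.5)
  expect_lt(i_depth / cell_depth, 1)  # interneurons far less modulated
})

test_that("classification handles silent, peak and degenerate cases", {
  rep0 <- structure(list(
    rate = matrix(c(0, 3, 1), 3, 1), infield_rate = matrix(c(0, 30, 1), 3, 1),
    n_laps = 1), class = "place_map_report")
  lab <- classify_place_cells(rep0)
  expect_equal(lab, c("silent", "active", "silent"))
  rep0$infield_rate[] <- 0
  expect_warning(lab0 <- classify_place_cells(rep0), "all cells silent")
  expect_true(all(lab0 == "silent"))
})

test_that("silencing requires labels and silenced cells emit no spikes", {
  net <- build_hippocampal_net(seed = 3)
  expect_error(run_silencing(net), "run exploration first")
  h <- hippo_short()
  sil <- run_silencing(h$ex$net, with_idip = TRUE)
  on_lap <- sil$spikes[sil$spikes$population == "CA1E" &
                         sil$spikes$time_ms > sil$net$state$t - 2 * 30000 &
                         sil$spikes$time_ms <= sil$net$state$t - 30000, ]
  silenced <- which(h$ex$net$labels == "active")
  expect_equal(sum(on_lap$neuron %in% silenced), 0)
})

test_that("compiled hippocampal engine matches the plain-R reference", {
  net <- build_hippocampal_net(seed = 6)
  dur <- 1500
  cpp <- sim_hippocampus_cpp(net$state, net$params, dur, 1, TRUE, TRUE,
                             logical(0), Inf)
  np <- neuron_params()
  pops <- list(CA3 = neuron_population(10, np),
               CA1E = neuron_population(100, np),
               CA1I = neuron_population(20, np))
  pops$CA3$v <- net$state$v_ca3
  pops$CA1E$v <- net$state$v_e
  pops$CA1I$v <- net$state$v_i
  pr <- net$params
  tune <- function(p, centers) {
    d <- abs(p - centers); d <- pmin(d, 100 - d)
    exp(-d^2 / (2 * pr$sigma_pc^2))
  }
  i_ext <- list(
    CA3 = function(t) pr$a_c * tune((pr$speed * t) %% 100, pr$centers_ca3),
    CA1E = function(t) pr$a_c * (tune((pr$speed * t) %% 100, pr$centers_e) +
                                   pr$offsets_e) + pr$i_ex_e,
    CA1I = function(t) rep(pr$i_ex_i, 20))
  projs <- list(
    ff = list(pre = "CA3", post = "CA1E",
              proj = synaptic_projection(10, 100, net$state$w_ff, exc_synapse()),
              rule = hebbian_rule(10, 100)),
    ie = list(pre = "CA1E", post = "CA1I",
              proj = synaptic_projection(100, 20, net$state$w_ie, exc_synapse())),
    ei = list(pre = "CA1I", post = "CA1E",
              proj = synaptic_projection(20, 100, net$state$w_ei, inh_synapse()),
              rule = idip_rule(20, eta = 1e-5, theta_in = 200)))
  ref <- run_network(pops, projs, i_ext = i_ext, duration = dur)
  key <- function(d) sort(paste(d$population, d$neuron, d$time_ms))
  cpp_sp <- spike_record(c("CA3", "CA1E", "CA1I")[cpp$spike_pop + 1],
                         cpp$spike_id, cpp$spike_t, dur)
  expect_identical(key(ref$spikes), key(cpp_sp))
  expect_equal(ref$projections$ff$proj$w, cpp$state$w_ff)
  expect_equal(ref$projections$ei$proj$w, cpp$state$w_ei)
})

test_that("the number of active place cells grows with the inhibitory target input", {
  n_active <- vapply(c(120, 200, 320), function(theta) {
    net <- build_hippocampal_net(seed = 3,
                                 idip = list(eta = 1e-5, theta_in = theta,
                                             tau = 160))
    ex <- run_exploration(net, n_laps = 10)
    sum(ex$net$labels == "active")
  }, 0)
  expect_true(all(diff(n_active) >= 0))
  expect_gt(n_active[3], n_active[1])
})
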