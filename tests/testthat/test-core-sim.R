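# Membrane, conductance and Poisson primitives of the simulation engine.

test_that("a neuron at threshold spikes, resets to rest and turns refractory", {
  pop <- neuron_population(3)
  pop$v <- c(-50, -49, -55)  # at, above and below threshold
  st <- step_membrane(pop, g_exc = 0, g_inh = 0, i_ext = 0, dt = 1)
  expect_equal(st$spiked, c(TRUE, TRUE, FALSE))
  expect_equal(st$pop$v[1:2], c(-60, -60))
  expect_equal(st$pop$refractory_remaining[1:2], c(2, 2))
  # held at rest and unable to spike while refractory, even with huge drive
  st2 <- step_membrane(st$pop, g_exc = 100, i_ext = 1, dt = 1)
  expect_false(any(st2$spiked[1:2]))
  expect_equal(st2$pop$v[1:2], c(-60, -60))
})

test_that("free membrane relaxes per the closed form, with O(dt) Euler error", {
  # V(t) = V_REST + (V0 - V_REST) exp(-t/tau_m), tau_m = 20 ms
  run_to <- function(dt, t_end, v0 = -55) {
    pop <- neuron_population(1)
    pop$v <- v0
    for (i in seq_len(round(t_end / dt))) {
      pop <- step_membrane(pop, 0, 0, 0, dt = dt)$pop
    }
    pop$v
  }
  exact <- -60 + 5 * exp(-1)  # deviation shrinks by factor e after 20 ms
  err1 <- abs(run_to(1, 20) - exact)
  err01 <- abs(run_to(0.1, 20) - exact)
  expect_lt(err1 / 5, 0.03)          # within a few % of the e-fold at dt = 1
  expect_lt(err01, err1 / 5)         # error shrinks ~linearly with dt
})

test_that("constant current drives V to the closed-form fixed point V_REST + R*I", {
  pop <- neuron_population(1)
  for (i in 1:600) pop <- step_membrane(pop, 0, 0, i_ext = 0.09, dt = 1)$pop
  expect_equal(pop$v, -60 + 100 * 0.09, tolerance = 1e-6)  # -51 mV, subthreshold
  # 0.1 nA would graze threshold exactly: V -> -60 + 100*0.1 = theta_m
  expect_equal(-60 + 100 * 0.1, neuron_params()$theta_m)
})

test_that("conductance jumps by g_bar*W per spike, decays by e per tau, masks hold", {
  proj <- synaptic_projection(2, 1, weight = matrix(c(2, 1), 1, 2),
                              params = exc_synapse(),
                              mask = matrix(c(TRUE, FALSE), 1, 2))
  expect_equal(proj$w[1, 2], 0)  # masked weight forced to zero
  proj <- step_conductance(proj, c(TRUE, FALSE), dt = 1)
  expect_equal(proj$g, 2)        # W_IE = 2.0 through g_bar = 1 nS
  g0 <- proj$g
  for (i in 1:5) proj <- step_conductance(proj, c(FALSE, FALSE), dt = 1)
  expect_equal(proj$g, g0 * exp(-1), tolerance = 1e-12)  # one tau_E = 5 ms
  # a spike through the masked (zero-weight) synapse leaves g unchanged
  g1 <- proj$g
  proj <- step_conductance(proj, c(FALSE, TRUE), dt = 1)
  expect_equal(proj$g, g1 * exp(-0.2), tolerance = 1e-12)
})

test_that("negative weights abort conductance stepping", {
  proj <- synaptic_projection(1, 1, 1)
  proj$w[1, 1] <- -0.5
  expect_error(step_conductance(proj, TRUE), "negative")
})

test_that("Poisson sources match their rate, are silent at 0 and reproducible", {
  src <- poisson_source(100, 10, rng_seed = 42)
  total <- 0
  for (i in 1:100000) total <- total + sum(draw_poisson_spikes(src, dt = 1))
  expect_equal(total / 100 / 100, 10, tolerance = 0.015)  # Hz over 100 s
  expect_false(any(draw_poisson_spikes(poisson_source(50, 0), dt = 1)))
  draw_all <- function(seed) {
    s <- poisson_source(20, 10, rng_seed = seed)
    replicate(200, draw_poisson_spikes(s, 1))
  }
  expect_identical(draw_all(7), draw_all(7))
  expect_false(identical(draw_all(7), draw_all(8)))
})

test_that("an unconnected quiet network stays exactly at rest", {
  pops <- list(A = neuron_population(5))
  out <- run_network(pops, projections = list(), duration = 100,
                     record_v = "A")
  expect_equal(nrow(out$spikes), 0)
  expect_true(all(out$v$A == -60))
})

test_that("protocol referencing an unknown population fails before simulating", {
  pops <- list(A = neuron_population(2))
  projs <- list(bad = list(pre = "A", post = "B",
                           proj = synaptic_projection(2, 2, 1)))
  expect_error(run_network(pops, projs, duration = 10), "unknown population")
})

test_that("spike records honor the refractory contract and voltage bounds", {
  set.seed(99)
  net <- build_recurrent_net(recurrent_net_spec(), seed = 99)
  res <- idipnet:::run_recurrent_chunk(net, 5000, rule = "none")
  expect_gt(min_isi(res$spikes, "E"), neuron_params()$t_ref)
  expect_gt(min_isi(res$spikes, "I"), neuron_params()$t_ref)
  expect_true(all(res$net$state$v_e >= -80 & res$net$state$v_e <= 0))
})

test_that("identical seeds and configs give identical event logs", {
  go <- function() {
    set.seed(123)
    net <- build_recurrent_net(recurrent_net_spec(), seed = 123)
    idipnet:::run_recurrent_chunk(net, 3000, rule = "idip", rule_on_ms = 1000)
  }
  a <- go(); b <- go()
  expect_identical(a$spikes$time_ms, b$spikes$time_ms)
  expect_identical(a$spikes$neuron, b$spikes$neuron)
  expect_identical(a$net$state$w_ei, b$net$state$w_ei)
})

test_that("compiled engine and plain-R reference produce identical dynamics", {
  set.seed(5)
  net <- build_recurrent_net(recurrent_net_spec(), seed = 5)
  n_steps <- 800
  ext <- matrix(runif(n_steps * 100) < 0.01, n_steps, 100)
  cpp <- idipnet:::run_recurrent_chunk(net, n_steps, rule = "idip",
                                       rule_on_ms = 300, ext_spikes = ext)
  rule <- idip_rule(20, eta = net$params$idip_eta,
                    theta_in = net$params$idip_theta_in,
                    tau = net$params$idip_tau,
                    update = "multiplicative", w_max = net$params$idip_w_max)
  parts <- r_engine_recurrent(net, ext, rule = rule)
  ref <- run_network(parts$populations, parts$projections, parts$sources,
                     duration = n_steps, rule_on_at = 300)
  key <- function(d) sort(paste(d$population, d$neuron, d$time_ms))
  expect_identical(key(ref$spikes), key(cpp$spikes))
  expect_equal(ref$projections$ei$proj$w, cpp$net$state$w_ei)
  expect_equal(ref$rules$ei$y, cpp$net$state$y)
})

test_that("the recurrent model without plasticity sits in the pathological regime", {
  set.seed(4)
  net <- build_recurrent_net(recurrent_net_spec(), seed = 4)
  st <- run_stabilization(net, rule = "none", duration = 20000,
                          record_final_ms = 10000)
  expect_gt(st$final_rate, 30)  # far above the few-Hz post-learning level
})
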