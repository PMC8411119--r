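# Rule-level behavior of IDIP (base + variants), Hebbian + homeostatic, and
# the iSTDP baseline.

test_that("IDIP trace follows its leaky-integral closed form", {
  # dy/dt = -y/tau + G  =>  y(t) = tau*G*(1 - exp(-t/tau)), fixed point tau*G
  G <- 2.5; tau <- 160
  st <- idip_rule(1, tau = tau)
  y_at <- c()
  for (t in 1:480) {
    st <- idip_update_trace(st, G, dt = 1)
    if (t %in% c(160, 320, 480)) y_at <- c(y_at, st$y)
  }
  expect_equal(y_at, tau * G * (1 - exp(-c(160, 320, 480) / tau)),
               tolerance = 0.01)
  for (t in 1:20000) st <- idip_update_trace(st, G, dt = 1)
  expect_equal(st$y, tau * G, tolerance = 1e-9)  # fixed point, exact for Euler
  # decay by factor e per tau once input is removed
  y0 <- st$y
  for (t in 1:tau) st <- idip_update_trace(st, 0, dt = 1)
  expect_equal(st$y / y0, exp(-1), tolerance = 0.005)
})

test_that("IDIP weight update is eta*(y - theta) per spike with a fixed point at theta", {
  st <- idip_rule(2, eta = 1e-5, theta_in = 200)
  st$y <- c(200, 300)
  w <- matrix(0.5, 4, 2)
  out <- idip_on_spike(st, c(TRUE, TRUE), w)
  expect_equal(out$w[, 1], rep(0.5, 4))            # y = theta: no change
  expect_equal(out$w[, 2], rep(0.5 + 1e-3, 4))     # eta*(300-200) = 1e-3
  # non-spiking neurons never update
  out2 <- idip_on_spike(st, c(FALSE, FALSE), w)
  expect_identical(out2$w, w)
})

test_that("multiplicative bound arithmetic matches the update equations", {
  st <- idip_rule(1, eta = 1, theta_in = 0, update = "multiplicative", w_max = 1)
  st$y <- 0.01   # raw dw = +0.01
  out <- idip_on_spike(st, TRUE, matrix(0.5, 1, 1))
  expect_equal(out$w[1, 1], 0.5 + (1 - 0.5) * 0.01)  # 0.505
  st$y <- -0.01  # raw dw = -0.01
  out <- idip_on_spike(st, TRUE, matrix(0.5, 1, 1))
  expect_equal(out$w[1, 1], 0.5 - 0.5 * 0.01)        # 0.495
})

test_that("multiplicative updates keep weights inside [0, w_max]", {
  set.seed(17)
  st <- idip_rule(1, eta = 1, theta_in = 0, update = "multiplicative", w_max = 1)
  w <- matrix(runif(6, 0.01, 0.99), 6, 1)
  for (k in 1:500) {
    st$y <- runif(1, -0.9, 0.9)  # large raw updates of both signs
    w <- idip_on_spike(st, TRUE, w)$w
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("holding y above theta makes outgoing inhibitory weights non-decreasing", {
  for (upd in c("additive", "multiplicative")) {
    st <- idip_rule(1, eta = 1e-4, theta_in = 100, update = upd, w_max = 10)
    st$y <- 180
    w <- matrix(0.2, 3, 1)
    for (k in 1:50) {
      w2 <- idip_on_spike(st, TRUE, w)$w
      expect_true(all(w2 >= w))
      w <- w2
    }
    st$y <- 40  # mirrored: below target, non-increasing
    for (k in 1:50) {
      w2 <- idip_on_spike(st, TRUE, w)$w
      expect_true(all(w2 <= w))
      w <- w2
    }
  }
})

test_that("zero learning rate conserves weights bitwise through a full run", {
  spec <- recurrent_net_spec(idip = list(eta = 0, theta_in = 550, tau = 160,
                                         w_max = 5))
  set.seed(31)
  net <- build_recurrent_net(spec, seed = 31)
  w0 <- net$state$w_ei
  res <- idipnet:::run_recurrent_chunk(net, 5000, rule = "idip", rule_on_ms = 0)
  expect_identical(res$net$state$w_ei, w0)
})

test_that("variant v2 with a fast trace approaches the base rule's cumulative update", {
  # two-neuron script: one inhibitory neuron with a prescribed spike train and
  # slowly varying trace input; compare cumulative weight change
  dt <- 0.1; tau_st <- 0.5
  spikes_at <- seq(50, 950, by = 60)
  steps <- seq(dt, 1000, by = dt)
  G <- 260 + 80 * sin(steps / 300)
  base <- idip_rule(1, eta = 1e-4, theta_in = 200)
  v2 <- idip_rule(1, eta = 1e-4 / tau_st, theta_in = 200, variant = "v2",
                  tau_st = tau_st)
  w_base <- matrix(1, 1, 1); w_v2 <- matrix(1, 1, 1)
  for (i in seq_along(steps)) {
    spk <- any(abs(steps[i] - spikes_at) < dt / 2)
    base <- idip_update_trace(base, G[i], dt = dt)
    v2 <- idip_update_trace(v2, G[i], dt = dt, spikes = spk)
    w_base <- idip_on_spike(base, spk, w_base, dt = dt)$w
    w_v2 <- idip_on_spike(v2, spk, w_v2, dt = dt)$w
  }
  d_base <- w_base[1, 1] - 1; d_v2 <- w_v2[1, 1] - 1
  expect_gt(abs(d_base), 0)
  expect_equal(d_v2, d_base, tolerance = 0.05)
})

test_that("variant v1 integrates the driving-force-weighted conductance", {
  st <- idip_rule(1, variant = "v1", tau = 160)
  st <- idip_update_trace(st, 2, dt = 1, v_post = -60, v_rev_exc = 0)
  expect_equal(st$y, 2 * 60)  # one Euler step: dt * G * (V_E - V)
  expect_error(idip_update_trace(idip_rule(1, variant = "v1"), 2),
               "membrane potentials")
})

test_that("variant v3 subtracts the inhibitory conductance sum", {
  st <- idip_rule(1, variant = "v3", tau = 160)
  st <- idip_update_trace(st, 5, dt = 1, g_inh_sum = 2)
  expect_equal(st$y, 3)
})

test_that("variant v4 shifts thresholds instead of weights", {
  st <- idip_rule(1, eta = 0.01, theta_in = 100, variant = "v4")
  st$y <- 150
  w <- matrix(0.5, 2, 1)
  out <- idip_on_spike(st, TRUE, w)
  expect_identical(out$w, w)
  expect_equal(out$dtheta, 0.01 * 50)
})

test_that("variant v5 updates by the rate-estimator error", {
  st <- idip_rule(1, eta = 1, variant = "v5", tau_est = 1000, theta_x = 5 / 1000)
  st$x_est <- 5  # estimated rate x/tau = 5/1000 = the target
  out <- idip_on_spike(st, TRUE, matrix(0.3, 1, 1))
  expect_equal(out$w[1, 1], 0.3)
  st$x_est <- 7
  out <- idip_on_spike(st, TRUE, matrix(0.3, 1, 1))
  expect_equal(out$w[1, 1], 0.3 + (7 / 1000 - 5 / 1000))
})

test_that("Hebbian rule has the printed fixed points and growth rate", {
  # all traces zero and row sum at target: both terms vanish
  st <- hebbian_rule(10, 1)
  w <- matrix(0.52, 1, 10)
  out <- hebbian_step(st, rep(FALSE, 10), FALSE, w)
  expect_equal(out$w, w)
  # a weight at w_max gets no Hebbian growth (soft bound)
  st2 <- hebbian_rule(1, 1, theta_homeo = 1.5)
  st2$x_pre <- 20 / 19; st2$x_post <- 20 / 19  # decays to exactly 1 this step
  out2 <- hebbian_step(st2, FALSE, FALSE, matrix(1.5, 1, 1))
  expect_equal(out2$w[1, 1], 1.5)
  # x_i = x_j = 1, w = 0, row sum at target: dw/dt = eta_hebb * w_max
  st3 <- hebbian_rule(2, 1)
  st3$x_pre <- c(20 / 19, 0); st3$x_post <- 20 / 19
  w3 <- matrix(c(0, 5.2), 1, 2)
  out3 <- hebbian_step(st3, c(FALSE, FALSE), FALSE, w3)
  expect_equal(out3$w[1, 1], 1e-3 * 1.5, tolerance = 1e-12)
  # weights clip at zero from below (row sum far above target, strong pull)
  st4 <- hebbian_rule(1, 1, eta_homeo = 10)
  out4 <- hebbian_step(st4, FALSE, FALSE, matrix(6, 1, 1))
  expect_equal(out4$w[1, 1], 0)
})

test_that("iSTDP updates match the printed per-spike equations", {
  # presyn spike when postsyn trace equals alpha: no change
  st <- istdp_rule(1, 1, eta = 5e-5, alpha = 0.2)
  st$x_post <- 0.2 * 20 / 19
  out <- istdp_step(st, TRUE, FALSE, matrix(0.5, 1, 1))
  expect_equal(out$w[1, 1], 0.5)
  # postsyn spike with presyn trace 0.5: dw = eta * x_pre = 2.5e-5
  st2 <- istdp_rule(1, 1, eta = 5e-5, alpha = 0.2)
  st2$x_pre <- 0.5 * 20 / 19
  out2 <- istdp_step(st2, FALSE, TRUE, matrix(0.5, 1, 1))
  expect_equal(out2$w[1, 1], 0.5 + 5e-5 * 0.5, tolerance = 1e-12)
  # without spikes traces decay by e per tau and weights hold
  st3 <- istdp_rule(1, 1)
  st3$x_pre <- 1
  w <- matrix(0.5, 1, 1)
  for (k in 1:20) {
    r <- istdp_step(st3, FALSE, FALSE, w)
    st3 <- r$state; w <- r$w
  }
  expect_equal(st3$x_pre, (1 - 1 / 20)^20, tolerance = 1e-12)
  expect_equal(st3$x_pre, exp(-1), tolerance = 0.03)
  expect_equal(w[1, 1], 0.5)
})

test_that("iSTDP drives a toy E/I circuit toward the rate implied by alpha", {
  # target rate = alpha / (2 * tau_iSTDP) = 0.2 / (2 * 20 ms) = 5 Hz
  set.seed(12)
  dur <- 80000
  drive <- matrix(runif(dur * 20) < 0.01, dur, 20)  # 20 units at 10 Hz
  parts <- toy_ei_circuit(drive, w_in = 2.7, w_ie = 3, eta = 5e-3)
  out <- run_network(parts$populations, parts$projections, parts$sources,
                     duration = dur)
  e_times <- out$spikes$time_ms[out$spikes$population == "E"]
  early <- sum(e_times <= 10000) / 10
  late <- sum(e_times > dur - 20000) / 20
  expect_gt(early, 15)              # unbalanced: far above target
  expect_lt(abs(late - 5), 3)       # converges toward ~5 Hz
  # brute-force scalar oracle of the same equations agrees
  oracle <- toy_ei_oracle(drive, w_in = 2.7, w_ie = 3, eta = 5e-3)
  late_o <- sum(oracle$spikes_e > dur - 20000) / 20
  expect_equal(late, late_o, tolerance = 1e-9)
  expect_equal(out$projections$ei$proj$w[1, 1], oracle$w, tolerance = 1e-9)
})
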