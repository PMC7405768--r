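test_that("depression multiplier follows the printed exponential recovery", {
  expect_equal(depression_multiplier(0), 0.88)
  expect_equal(depression_multiplier(Inf), 1)
  expect_equal(depression_multiplier(20), 1 - 0.12 * exp(-1))
  expect_error(depression_multiplier(-1), "dt_ms")
  # bounded and monotone over a dense grid
  dts <- seq(0, 200, by = 0.5)
  m <- depression_multiplier(dts)
  expect_true(all(m >= 0.88 & m <= 1))
  expect_true(all(diff(m) > 0))
  # effect essentially gone after ~40 ms
  expect_gt(depression_multiplier(40), 0.98)
})

test_that("threshold adaptation jumps 20% and relaxes 90% in 10 ms", {
  expect_equal(threshold_trace(numeric(0), 5), 1)
  expect_equal(threshold_trace(0, 0), 1.2)
  expect_equal(threshold_trace(0, 10), 1.02)
  expect_error(threshold_trace(5, 3), "last spike")
  # relaxation contract holds for arbitrary spike histories:
  # excess(t + 10) = 0.1 * excess(t)
  set.seed(1)
  for (rep in 1:5) {
    sp <- sort(runif(10, 0, 50))
    t0 <- 50 + runif(1, 0, 5)
    ex_t <- threshold_trace(sp, t0) - 1
    ex_t10 <- threshold_trace(sp, t0 + 10) - 1
    expect_equal(ex_t10, 0.1 * ex_t, tolerance = 1e-12)
  }
  expect_true(all(threshold_trace(c(1, 2, 3), seq(3, 30)) >= 1))
})

test_that("L6 response function hits its floor and ceiling anchors", {
  cfg <- default_config("mini")
  f_sp <- l6_response(cfg$l6$spont_l4_rate, midpoint = cfg$l6$midpoint,
                      slope = cfg$l6$slope)
  f_pk <- l6_response(cfg$l6$peak_l4_rate, midpoint = cfg$l6$midpoint,
                      slope = cfg$l6$slope)
  expect_equal(f_sp, 5, tolerance = 0.2)    # ~5 sp/s at spontaneous L4 rate
  expect_equal(f_pk, 80, tolerance = 0.1)   # ~80 sp/s at peak L4 rate
  r <- seq(0, 60, by = 0.5)
  expect_true(all(diff(l6_response(r)) > 0))  # monotone sigmoid
  expect_error(l6_response(-2), "nonnegative")
})

test_that("L6 facilitation is anchored at (30, 1.0) and (60, 1.1)", {
  expect_equal(l6_facilitation(30), 1)
  expect_equal(l6_facilitation(60), 1.1)
  expect_equal(l6_facilitation(60) / l6_facilitation(30), 1.1)
  x <- l6_facilitation(45)
  expect_true(x > 1 && x < 1.1)
  # clamped outside the calibrated range
  expect_equal(l6_facilitation(0), l6_facilitation(-0 + 1e-12))
  expect_equal(l6_facilitation(200), l6_facilitation(90))
  expect_true(all(diff(l6_facilitation(seq(0, 120, 5))) >= 0))
})

test_that("local L4 rate estimation counts disk members over the window", {
  neurons <- data.frame(id = 1:3, x_um = c(0, 50, 80), y_um = 0)
  rec0 <- data.frame(neuron = integer(0), t_ms = numeric(0))
  expect_equal(local_l4_rate(rec0, neurons, c(0, 0), 100), 0)
  # neuron 3 at 80 um is outside the 75 um disk: its spikes are ignored
  rec <- data.frame(neuron = c(1, 2, 3, 3, 3), t_ms = c(60, 80, 55, 70, 95))
  # 2 spikes from members {1, 2} in (50, 100] / (2 neurons * 0.05 s)
  expect_equal(local_l4_rate(rec, neurons, c(0, 0), 100), 2 / (2 * 0.05))
  expect_error(local_l4_rate(rec, neurons, c(5000, 0), 100), "no neurons")
  expect_error(local_l4_rate(rec, neurons, c(0, 0), 20), "window")
})

test_that("local rate estimator recovers a known Poisson population rate", {
  set.seed(42)
  n <- 60
  neurons <- data.frame(id = 1:n, x_um = runif(n, -40, 40),
                        y_um = runif(n, -40, 40))
  # homogeneous Poisson at 10 sp/s for 2 s
  rec <- do.call(rbind, lapply(1:n, function(i) {
    k <- rpois(1, 20)
    if (k == 0) NULL else data.frame(neuron = i, t_ms = sort(runif(k, 0, 2000)))
  }))
  est <- vapply(seq(500, 2000, by = 250), function(t)
    local_l4_rate(rec, neurons, c(0, 0), t, radius_um = 75, window_ms = 500), 1)
  expect_equal(mean(est), 10, tolerance = 0.2)
})

test_that("frozen-rate L6 spiking respects failures, rates and facilitation", {
  targets <- list(1:5, 6:8)
  # failure probability 1: nothing is delivered
  ev <- l6_spike_step(c(40, 40), targets, 1000, fail = 1, seed = 1)
  expect_equal(nrow(ev), 0)
  # failure 0.5 delivers about half of the emitted synaptic events
  ev0 <- l6_spike_step(c(60, 30), targets, 20000, fail = 0, seed = 3)
  ev5 <- l6_spike_step(c(60, 30), targets, 20000, fail = 0.5, seed = 3)
  expect_equal(nrow(ev5) / nrow(ev0), 0.5, tolerance = 0.1)
  # emitted spike counts match the Poisson mean at the frozen rate
  n1 <- length(unique(ev0$t_ms[ev0$unit == 1]))
  expect_lt(abs(n1 - 60 * 20), 3 * sqrt(60 * 20) + 1)
  # facilitation multiplier follows the unit's rate
  expect_equal(unique(ev0$weight_mult[ev0$unit == 1]), 1.1)
  expect_equal(unique(ev0$weight_mult[ev0$unit == 2]), 1.0)
  expect_identical(l6_spike_step(c(10, 10), targets, 500, seed = 9),
                   l6_spike_step(c(10, 10), targets, 500, seed = 9))
})

test_that("integrate_step: leak decay, fixed point, spike/reset", {
  # pure leak: monotone decay toward 0
  st <- list(v = 0.5)
  vs <- numeric(20)
  for (k in 1:20) { st <- integrate_step(st, dt_ms = 1); vs[k] <- st$v }
  expect_true(all(diff(c(0.5, vs)) < 0))
  expect_true(all(vs > 0))
  # conductances chosen so the net current vanishes at v = 0.5: fixed point
  g_i <- 10
  g_e <- (10 * (0.5 - (-2 / 3)) + 50 * 0.5) / (14 / 3 - 0.5)
  st <- list(v = 0.5, g_e = g_e, g_i = g_i)
  st <- integrate_step(st, dt_ms = 5)
  expect_equal(st$v, 0.5, tolerance = 1e-10)
  # suprathreshold drive spikes and resets
  st <- list(v = 0.99, g_e = 200, g_i = 0)
  st <- integrate_step(st, dt_ms = 1)
  expect_true(st$spiked)
  expect_equal(st$v, 0)
})

test_that("compiled integrator matches the closed-form LIF solution", {
  # one neuron, constant excitatory conductance, all mechanisms off:
  # v(t) = Vinf (1 - exp(-G t)), Vinf = gE VE / G, G = gL + gE.
  # Closed-form interspike interval: t* = -log(1 - 1/Vinf)/G (+ refractory).
  gE <- 30
  gL <- 50
  VE <- 14 / 3
  G <- gL + gE
  Vinf <- gE * VE / G
  t_star <- -log(1 - 1 / Vinf) / G          # seconds
  ref_ms <- 2
  par <- list(dt_ms = 0.1, n_steps = 20000L, rec_start_ms = 0,
              g_leak = gL, V_E = VE, V_I = -2 / 3, tau_e_ms = 3,
              tau_i_ms = 5, delay_e_ms = 1, delay_i_ms = 0.5,
              ref_e_ms = ref_ms, ref_i_ms = 1,
              S_ee = 0, S_ie = 0, S_ei = 0, S_ii = 0, S_lgn_e = 0,
              S_lgn_i = 0, S_l6_e = 0, S_l6_i = 0, S_amb = 0,
              amb_rate_e = 0, amb_rate_i = 0, dep_frac = 0.12,
              dep_tau_ms = 20, thr_jump = 0.2, thr_tau_ms = 10 / log(10),
              enable_depression = FALSE, enable_thr_adapt = FALSE,
              enable_l6 = FALSE, l6_floor = 5, l6_ceil = 80, l6_mid = 20,
              l6_slope = 2, l6_fail = 0.5, l6_scale = 1, l6_update_ms = 5,
              l6_window_ms = 50, record_currents = FALSE,
              gE_const = gE, gI_const = 0, v_init = 0,
              record_v_ids = integer(0))
  z <- integer(0)
  res <- v1net:::run_network_cpp(1L, c(0L, 0L), z, z, z, c(0L, 0L), z,
                                 0L, z, c(0L, 0L), z, z, par)
  isi <- diff(res$spike_t_ms) / 1000
  expect_gt(length(isi), 10)
  expect_equal(mean(isi), t_star + ref_ms / 1000, tolerance = 0.01)
  expect_lt(sd(isi), 1e-9)   # perfectly regular without noise
})

test_that("network simulation is reproducible and books currents by source", {
  sim1 <- get_mini_sim()
  sim2 <- run_simulation(get_mini_net(), grating_spec(contrast = 0),
                         duration_s = 1.5, seed = 11, record_from_s = 0.5)
  expect_identical(sim1$record, sim2$record)
  expect_identical(sim1$currents, sim2$currents)
  cur <- sim1$currents
  # excitatory sources depolarise, GABA and leak hyperpolarise
  expect_true(all(cur$lgn >= 0) && all(cur$l4e >= 0) && all(cur$l6 >= 0) &&
                all(cur$amb >= 0))
  expect_true(all(cur$gaba <= 0))
  # leak opposes the mean depolarisation (individual hyperpolarised cells
  # can have a positive leak current, since v may sit below rest)
  expect_lt(mean(cur$leak), 0)
  # excitation and inhibition nearly cancel: what remains of the net
  # membrane current is a small positive excess that drives spiking and is
  # correlated with the neuron's firing rate
  net_cur <- rowSums(cur[, c("lgn", "l4e", "l6", "amb", "gaba", "leak")])
  rates <- mean_rates(sim1)$rate_sps
  expect_gt(mean(net_cur), 0)
  expect_lt(mean(net_cur), 0.2 * mean(rowSums(cur[, c("lgn", "l4e", "l6", "amb")])))
  expect_gt(cor(net_cur, rates), 0.5)
})

test_that("background activity is asynchronous with I above E", {
  sim <- get_mini_sim()
  nt <- get_mini_net()$neurons
  r <- mean_rates(sim)$rate_sps
  re <- mean(r[nt$cls == "E"])
  ri <- mean(r[nt$cls == "I"])
  expect_gt(re, 1); expect_lt(re, 30)
  expect_gt(ri / re, 2); expect_lt(ri / re, 7)
  # far from full population spikes: 5-ms participation stays low
  frac <- summed_spike_fraction(sim$record, nt$id[nt$cls == "E"],
                                t_range = c(500, 1500))
  expect_lt(max(frac$fraction), 0.5)
  expect_lt(quantile(frac$fraction, 0.9), 0.2)
})
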