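# Chemical synapses, short-term depression, gap junctions, Poisson drive.

test_that("transmitter pulses are delayed, brief and saturating", {
  expect_equal(transmitter_concentration(numeric(0), c(0, 10, 20)), c(0, 0, 0))
  # one spike at 10 ms, 2 ms delay: 0.5 mM on [12, 12.3)
  tt <- c(11.9, 12, 12.2, 12.29, 12.31)
  expect_equal(transmitter_concentration(10, tt), c(0, 0.5, 0.5, 0.5, 0))
  # overlapping pulses form a union with unchanged amplitude
  expect_equal(max(transmitter_concentration(c(10, 10.1), seq(11, 13, 0.01))),
               0.5)
  expect_error(transmitter_concentration(c(5, 1), 0), "sorted")
})

test_that("synaptic gating follows first-order transmitter binding", {
  k <- synapse_constants()
  # free decay matches exp(-beta t)
  s <- 0.8
  for (i in 1:500) s <- syn_gating_step(s, 0, "AMPA", dt = 0.02)
  expect_equal(s, 0.8 * exp(-k$beta[["AMPA"]] * 10), tolerance = 1e-8)
  # constant transmitter: fixed point alpha T/(alpha T + beta) ~ 0.723
  s <- 0
  for (i in 1:4000) s <- syn_gating_step(s, 0.5, "AMPA", dt = 0.02)
  expect_equal(s, 0.47 / (0.47 + 0.18), tolerance = 1e-6)
  # absorbing zero
  expect_equal(syn_gating_step(0, 0, "GABAA"), 0)
})

test_that("the magnesium block is a sigmoid with midpoint -25 mV", {
  expect_equal(mg_block(-25), 0.5)
  expect_equal(mg_block(-87.5), 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(mg_block(1e3), 1, tolerance = 1e-10)
  v <- seq(-100, 40, 5)
  expect_true(all(diff(mg_block(v)) > 0))
})

test_that("short-term depression recovers between and depletes at spikes", {
  s0 <- list(D_i = 1, t_i = -Inf)
  expect_equal(depression_update(s0, 1000), 1)
  s1 <- depression_update(s0, 0, is_spike = TRUE)
  # immediately after a spike from D = 1 the available fraction is 0.93
  expect_equal(depression_update(s1, 1e-9), 0.93, tolerance = 1e-6)
  expect_equal(depression_update(s1, 1e5), 1, tolerance = 1e-10)
  expect_error(depression_update(s1, -1), "backwards")
  # periodic 100 ms spiking: iterate the spike-to-spike map to its fixed
  # point and compare with the closed form (1-e^(-1/7))/(1-0.93 e^(-1/7))
  st <- list(D_i = 1, t_i = -Inf)
  t <- 0
  d_pre <- NA
  for (i in 1:200) {
    d_pre <- depression_update(st, t)
    st <- depression_update(st, t, is_spike = TRUE)
    t <- t + 100
  }
  q <- exp(-100 / 700)
  expect_equal(d_pre, (1 - q) / (1 - 0.93 * q), tolerance = 1e-9)
  expect_equal(d_pre, 0.687, tolerance = 1e-3)
  # with U = 0, D stays 1
  st <- list(D_i = 1, t_i = -Inf)
  for (t in seq(0, 1000, 50)) st <- depression_update(st, t, TRUE, U = 0)
  expect_equal(depression_update(st, 1001, U = 0), 1)
})

test_that("chemical and gap-junction currents follow their closed forms", {
  expect_equal(chem_current(3, s = 0, D = 1, v_post = -50, E_syn = -80), 0)
  expect_equal(chem_current(3, s = 0.7, D = 0.9, v_post = -80, E_syn = -80), 0)
  # GABA_A onto a TC cell: 3 nS * 0.5 * 30 mV = 45 pA = 0.045 nA
  expect_equal(chem_current(3, s = 0.5, D = 1, v_post = -50, E_syn = -80),
               0.045)
  # NMDA applies the magnesium block
  expect_equal(chem_current(2, 0.5, 1, -25, 0, nmda = TRUE),
               1e-3 * 2 * 0.5 * 0.5 * -25)
  expect_equal(gap_current(-60, -60, 100), 0)
  expect_equal(gap_current(-50, -80, 100), gap_current(-80, -50, 100) * -1)
  expect_equal(gap_current(-50, -80, 100), -0.3)  # 30 mV / 100 MOhm
})

test_that("Poisson input conductance is shot noise with 5 ms decay", {
  expect_equal(poisson_conductance(numeric(0), c(0, 5), 1), c(0, 0))
  g <- poisson_conductance(0, c(0, 5, 10), 2)
  expect_equal(g, 2 * exp(-c(0, 5, 10) / 5))
  # long-run mean = rate * g_input * tau = 0.5 * g_input at 100 Hz
  set.seed(42)
  ev <- poisson_events(100, 1e5)
  gbar <- mean(poisson_conductance(ev, seq(1000, 99000, by = 37), 1))
  expect_equal(gbar, 0.5, tolerance = 0.05)
  # event count over 10 s within 3 sd of 1000
  set.seed(7)
  counts <- replicate(20, length(poisson_events(100, 1e4)))
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1000)))
})
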