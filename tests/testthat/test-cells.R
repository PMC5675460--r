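# Single-cell machinery: gating kinetics, channel currents, calcium
# handling, and the membrane equation.

test_that("gating steady states and time constants are well formed", {
  v <- seq(-120, 60, by = 0.5)
  for (type in c("HTC", "RTC", "IN", "RE")) {
    for (ch in channels_for(type)) {
      for (gate in list(ch$m, ch$h)) {
        if (is.null(gate)) next
        g <- eval_gating(gate, v, ca = 0.05)
        expect_true(all(g$x_inf >= 0 & g$x_inf <= 1),
                    info = paste(type, gate$name))
        expect_true(all(g$tau > 0), info = paste(type, gate$name))
      }
    }
  }
})

test_that("rate-form gating gives alpha/(alpha+beta) and its symmetry point", {
  spec <- gating_spec("sym",
                      alpha = function(v, ca) rep(2, length(v)),
                      beta = function(v, ca) rep(2, length(v)))
  g <- eval_gating(spec, 0)
  expect_equal(g$x_inf, 0.5)
  expect_equal(g$tau, 1 / 4)
  expect_error(eval_gating(spec, NaN), "non-finite")
  expect_error(eval_gating(spec, 0, ca = -1), "calcium")
})

test_that("high-threshold T kinetics equal low-threshold kinetics shifted 28 mV", {
  lo_m <- kin_tc_t_m(); hi_m <- kin_tc_t_m(shift = 28)
  lo_h <- kin_tc_t_h(); hi_h <- kin_tc_t_h(shift = 28)
  v <- seq(-90, 20, by = 1)
  expect_equal(eval_gating(hi_m, v)$x_inf, eval_gating(lo_m, v - 28)$x_inf)
  expect_equal(eval_gating(hi_h, v)$tau, eval_gating(lo_h, v - 28)$tau)
})

test_that("gating tables reproduce x_inf = B/A on the grid", {
  specs <- list(kin_tc_t_m(), kin_h_m(), kin_na_m())
  tab <- gating_tables(specs, v_min = -100, v_max = 40, dv = 0.5)
  expect_equal(tab$B / tab$A, tab$X, tolerance = 1e-12)
  expect_true(all(tab$A > 0))
})

test_that("calcium Nernst potential matches direct evaluation", {
  # equal concentrations: zero
  expect_equal(nernst_eca(2000), 0)
  # resting concentration: (RT/2F) ln(4e4), about +141.2 mV
  slope <- 1e3 * 8.31441 * 309.15 / (2 * 96489)
  expect_equal(nernst_eca(0.05), slope * log(2000 / 0.05), tolerance = 1e-12)
  expect_equal(nernst_eca(0.05), 141.15, tolerance = 0.05)
  # halving the concentration raises E_Ca by (RT/2F) ln 2 ~ 9.23 mV
  expect_equal(nernst_eca(0.1) - nernst_eca(0.2), slope * log(2),
               tolerance = 1e-12)
  expect_equal(nernst_eca(0.1) - nernst_eca(0.2), 9.23, tolerance = 0.01)
  # monotone decreasing
  ca <- c(0.05, 0.5, 5, 50)
  expect_true(all(diff(nernst_eca(ca)) < 0))
  expect_error(nernst_eca(0), "calcium")
})

test_that("channel currents follow g m^p h^q (V - E)", {
  ch <- channels_for("HTC")
  na <- ch[[which(vapply(ch, `[[`, "", "name") == "Na")]]
  expect_equal(channel_current(na, -20, m = 0, h = 1), 0)
  expect_equal(channel_current(na, 50, m = 0.5, h = 0.5), 0)  # V = E_Na
  expect_equal(channel_current(na, -20, m = 0.5, h = 0.8),
               na$g * 0.5^3 * 0.8 * (-20 - 50))
  can <- ch[[which(vapply(ch, `[[`, "", "name") == "CAN")]]
  # half-saturation of the Michaelis-Menten factor at 0.2 uM
  expect_equal(channel_current(can, -30, m = 0.4, ca = 0.2),
               0.5 * can$g * 0.4 * (-30 - 10))
  expect_error(channel_current(na, 0, m = 1.5), "gating")
})

test_that("calcium dynamics relax to rest and to the loaded steady state", {
  p <- cell_params("HTC")
  expect_equal(calcium_derivative(0, 0.05, p), 0)
  # independent forward-Euler integration as oracle for the steady state
  i_ca <- -2  # uA/cm2 inward
  ca <- 0.05
  for (i in 1:20000) ca <- ca + 0.01 * calcium_derivative(i_ca, ca, p)
  k <- 1e-6 / (2 * 96489 * 0.5e-4) * 1e6
  expect_equal(ca, 0.05 - p$tau_ca * i_ca * k, tolerance = 1e-6)
  # with channels off, decay toward 0.05: within 1% of the gap per 5 tau
  ca <- 1
  for (i in 1:(5 * p$tau_ca * 100)) ca <- ca + 0.01 * calcium_derivative(0, ca, p)
  expect_lt(abs(ca - 0.05), 0.01 * (1 - 0.05))
})

test_that("membrane equation has the stated leak fixed point and scaling", {
  p <- cell_params("HTC", g_KL = 0.035, g_L = 0.01)
  v_fp <- leak_fixed_point(p)
  expect_equal(v_fp, (0.01 * -70 + 0.035 * -90) / 0.045)
  expect_equal(v_fp, -85.56, tolerance = 0.01)
  # all channels closed: derivative vanishes at the fixed point
  gates <- list()
  expect_equal(membrane_derivative(v_fp, gates, 0.05, p), 0, tolerance = 1e-12)
  # 1 nA of synaptic current on a TC cell is 1e-3/2.9e-4 ~ 3.45 uA/cm2
  dv0 <- membrane_derivative(v_fp, gates, 0.05, p)
  dv1 <- membrane_derivative(v_fp, gates, 0.05, p, i_syn = 1)
  expect_equal(dv0 - dv1, 1e-3 * 1 / 2.9e-4, tolerance = 1e-9)
})

test_that("a passive cell under current clamp stays at the fixed point", {
  zero <- c(Na = 0, DR = 0, CaT = 0, CaHT = 0, CaL = 0, H = 0, AHP = 0,
            CAN = 0)
  cc <- current_clamp("HTC", duration = 200, g_KL = 0.035, densities = zero)
  p <- cell_params("HTC", g_KL = 0.035)
  expect_lt(max(abs(cc$v - leak_fixed_point(p))), 1e-6)
  expect_length(cc$spikes, 0)
})

test_that("HTC firing mode depends on the neuromodulatory state", {
  # low ACh/NE: spontaneous rhythmic low-threshold events near the delta band
  lo <- current_clamp("HTC", duration = 3000, g_KL = 0.035)
  ev <- lo$spikes[lo$spikes > 1000]
  expect_gt(length(ev), 3)
  isi <- diff(ev)
  expect_gt(median(isi), 140)   # < 7 Hz
  expect_lt(median(isi), 500)   # > 2 Hz
  expect_lt(stats::sd(isi) / mean(isi), 0.3)  # rhythmic, not random
  # medium ACh/NE: rebound burst after release from hyperpolarization
  md <- current_clamp("HTC",
                      steps = data.frame(amplitude = -0.05, onset = 1000,
                                         offset = 2000),
                      duration = 2600, g_KL = 0.01)
  expect_gt(sum(md$spikes > 2000 & md$spikes < 2400), 0)
})

test_that("shipped parameter files round-trip into cell parameters", {
  for (ty in c("HTC", "IN", "RE")) {
    p_file <- read_cell_params(ty)
    p_code <- cell_params(ty)
    g_file <- vapply(p_file$channels, `[[`, numeric(1), "g")
    g_code <- vapply(p_code$channels, `[[`, numeric(1), "g")
    expect_equal(g_file, g_code)
    expect_equal(p_file$area, p_code$area)
  }
})
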