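# The fixed-step RK4 engine: determinism, decoupling, stationarity,
# convergence, and state-variable bounds.

no_coupling_rules <- function() {
  r <- connectivity_rules()
  r$chem$p[] <- 0
  r$gap$p[] <- 0
  r
}

zero_drive <- c(HTC = 0, RTC = 0, IN = 0, RE = 0)

test_that("zero duration yields an empty recording", {
  net <- small_network(seed = 1)
  st <- params_for_named_state("delta")
  rec <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 0,
                           discard = 0, seed = 1)
  expect_equal(nrow(rec$spikes), 0)
})

test_that("identical seeds give identical spike rasters", {
  net <- small_network(seed = 4)
  st <- params_for_named_state("delta")
  a <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 800,
                         discard = 0, seed = 9)
  b <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 800,
                         discard = 0, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$mean_v, b$mean_v)
  d <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 800,
                         discard = 0, seed = 10)
  expect_false(identical(a$spikes, d$spikes))
})

test_that("an uncoupled network reproduces the isolated-cell trajectory", {
  net <- build_network(seed = 1, sizes = small_sizes,
                       rules = no_coupling_rules(), heterogeneity = FALSE)
  rec <- simulate_thalamus(net, params_for_named_state("delta")$g_KL,
                           zero_drive, duration = 1000, discard = 0,
                           seed = 1, input_rate = 0, stride_ms = 0.1,
                           traces = data.frame(pop = "HTC", cell = 3))
  cc <- current_clamp("HTC", duration = 1000, g_KL = 0.035)
  expect_lt(max(abs(rec$traces[, 1] - cc$v)), 1e-9)
})

test_that("a passive network at its fixed point is stationary", {
  zero <- c(Na = 0, DR = 0, CaT = 0, CaHT = 0, CaL = 0, H = 0, AHP = 0,
            CAN = 0)
  zero_in <- zero[-c(3, 5)]  # IN has no CaT/CaL
  zero_re <- zero[-c(4, 5, 6)]
  net <- build_network(seed = 1, sizes = small_sizes,
                       rules = no_coupling_rules(), heterogeneity = FALSE)
  rec <- simulate_thalamus(net, params_for_named_state("delta")$g_KL,
                           zero_drive, duration = 10, discard = 0, seed = 1,
                           input_rate = 0,
                           densities = list(HTC = zero, RTC = zero,
                                            IN = zero_in, RE = zero_re))
  drift <- apply(rec$mean_v, 2, function(v) max(abs(v - v[1])))
  expect_lt(max(drift), 1e-9)
})

test_that("the integrator converges at fourth order on smooth dynamics", {
  # smooth relaxation (only leaks and the h-current active, driven by a
  # 50 pA step): halving the step must shrink the trace error by about 2^4
  dens <- c(Na = 0, DR = 0, CaT = 0, CaHT = 0, CaL = 0, AHP = 0, CAN = 0)
  stp <- data.frame(amplitude = 0.05, onset = 20, offset = 120)
  tr <- function(dt) current_clamp("HTC", steps = stp, duration = 200,
                                   g_KL = 0.035, densities = dens,
                                   dt = dt)$v
  ref <- tr(0.0025)
  e_coarse <- max(abs(tr(0.05) - ref))
  e_fine <- max(abs(tr(0.025) - ref))
  # fourth-order shrinkage, unless both errors already sit at the
  # rate-table interpolation floor
  expect_true(e_fine < e_coarse / 8 || e_fine < 1e-8)
})

test_that("halving the step leaves single-cell spike times stable", {
  a <- current_clamp("HTC", duration = 1000, g_KL = 0.035, dt = 0.02)
  b <- current_clamp("HTC", duration = 1000, g_KL = 0.035, dt = 0.01)
  expect_equal(length(a$spikes), length(b$spikes))
  # within a quarter millisecond over a second of slow bursting
  expect_lt(max(abs(a$spikes - b$spikes)), 0.25)
})

test_that("gating, synaptic and calcium state stay inside their bounds", {
  net <- small_network(seed = 2)
  st <- params_for_named_state("delta")
  rec <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 1000,
                           discard = 0, seed = 3, check = TRUE)
  expect_gte(rec$diag$gate_min, 0)
  expect_lte(rec$diag$gate_max, 1)
  expect_gt(rec$diag$ca_min, 0)
  expect_lte(rec$diag$s_max, 1)
  expect_gt(nrow(rec$spikes), 0)
  # spike times strictly increasing per cell with >= 1.5 ms separation
  by_cell <- split(rec$spikes$time, paste(rec$spikes$pop, rec$spikes$cell))
  gaps <- unlist(lapply(by_cell, diff))
  if (length(gaps)) expect_gte(min(gaps), 1.5)
})

test_that("a zero-amplitude stimulus leaves the dynamics untouched", {
  net <- small_network(seed = 6)
  st <- params_for_named_state("alpha")
  plain <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 600,
                             discard = 0, seed = 5)
  wave <- numeric(round(600 / 0.02) + 1)
  stim <- simulate_thalamus(net, st$g_KL, st$g_input, duration = 600,
                            discard = 0, seed = 5,
                            stimulus = list(wave = wave,
                                            targets = c("HTC", "RTC", "IN")))
  expect_identical(plain$spikes, stim$spikes)
})
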