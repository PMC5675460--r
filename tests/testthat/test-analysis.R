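# Analysis toolchain, exercised on synthetic signals and spike trains.

sine_rec <- function(freq, amp = 1, dur_s = 3, fs = 1000, noise = 0,
                     discard = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t) + rnorm(length(t), 0, noise)
  synthetic_recording(x, fs = fs, discard = discard)
}

test_that("the sLFP filter removes DC and passes the band", {
  set.seed(1)
  rec <- synthetic_recording(rep(-65, 3000))
  sl <- compute_slfp(rec)
  expect_lt(max(abs(sl$x)), 1e-6)
  # 10 Hz passes at about unit gain
  rec <- sine_rec(10, amp = 2)
  sl <- compute_slfp(rec)
  mid <- sl$x[500:2500]
  expect_equal(max(mid), 2, tolerance = 0.1)
  # 100 Hz is attenuated by more than 20 dB
  rec <- sine_rec(100, amp = 2, fs = 1000)
  sl <- compute_slfp(rec)
  expect_lt(max(abs(sl$x[500:2500])), 2 / 10)
  expect_error(compute_slfp(synthetic_recording(rnorm(100))), "short")
})

test_that("dominant frequency is the spectral argmax over the band", {
  set.seed(2)
  rec <- sine_rec(10, amp = 1.5)
  pk <- dominant_frequency(compute_slfp(rec))
  expect_equal(pk$frequency, 10, tolerance = 0.2)
  expect_equal(pk$power, 1.5^2 / 2, tolerance = 0.15)
  # larger amplitude wins
  t <- seq(0, 2.999, by = 1e-3)
  x <- 2 * sin(2 * pi * 5 * t) + 1 * sin(2 * pi * 20 * t)
  expect_equal(dominant_frequency(x, fs = 1000)$frequency, 5, tolerance = 0.2)
  # recovery across the 1-50 Hz range within one frequency-grid bin
  for (f in c(1.5, 4, 9, 17, 33, 49)) {
    est <- dominant_frequency(sin(2 * pi * f * t), fs = 1000)$frequency
    expect_equal(est, f, tolerance = 0.1)
  }
})

test_that("spike phases are measured against -sLFP peaks", {
  t <- seq(0, 2.999, by = 1e-3)
  x <- sin(2 * pi * 5 * t)  # -x peaks at t = 150, 350, ... ms
  sl <- structure(list(t = t * 1000, x = x, fs = 1000, band = c(0.5, 80)),
                  class = "slfp")
  circ0 <- function(ph) pmin(abs(ph), abs(2 * pi - ph))  # distance from 0
  ph <- spike_phases(c(350, 550), sl)
  expect_lt(max(circ0(ph)), 0.05)
  ph <- spike_phases(c(250, 450), sl)          # sLFP maxima: midpoints
  expect_equal(ph, c(pi, pi), tolerance = 0.05)
  # spikes at sLFP troughs are peaks of -sLFP: phase 0
  troughs <- 1000 * (0.15 + 0.2 * (0:5))
  expect_lt(max(circ0(spike_phases(troughs, sl))), 0.05)
})

test_that("the synchronization index matches the circular resultant", {
  expect_equal(sync_index(rep(1.3, 25)), 1)
  expect_equal(sync_index(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(sync_index(seq(0, 2 * pi, length.out = 13)[-13]), 0,
               tolerance = 1e-12)
  expect_true(is.na(sync_index(numeric(0))))
  set.seed(3)
  for (i in 1:10) {
    phi <- runif(50, 0, 2 * pi)
    oracle <- Mod(mean(complex(modulus = 1, argument = phi)))
    expect_equal(sync_index(phi), oracle, tolerance = 1e-12)
  }
})

test_that("PETH cross-correlation peaks where it should", {
  set.seed(4)
  a <- sort(runif(400, 0, 4000))
  same <- peth_crosscorr(a, a, 0, 4000)
  expect_equal(same$peak, 1, tolerance = 1e-9)
  expect_equal(same$lag, 0)
  shifted <- peth_crosscorr(a, a + 10, 0, 4000)
  expect_equal(shifted$lag, 10, tolerance = 2)
  expect_gt(shifted$peak, 0.8)
  b <- sort(runif(400, 0, 4000))
  expect_lt(abs(peth_crosscorr(a, b, 0, 4000)$peak), 0.35)
  expect_true(is.na(peth_crosscorr(numeric(0), a, 0, 4000)$peak))
})

test_that("burst segmentation follows the 10 ms ISI rule", {
  even <- seq(0.5, 999.5, length.out = 30)  # 30 spikes over 1 s
  st <- firing_and_burst_stats(even, 0, 1000)
  expect_equal(st$rate, 30)
  expect_equal(st$n_bursts, 0)
  # 4 triplets per second with 5 ms intra-burst ISI
  trip <- as.vector(outer(c(0, 5, 10), seq(100, 850, by = 250), "+"))
  st <- firing_and_burst_stats(sort(trip), 0, 1000)
  expect_equal(st$burst_freq, 4)
  expect_equal(st$spikes_per_burst, 3)
})

test_that("the state classifier follows the three-step procedure", {
  set.seed(5)
  # steady 9 Hz, high power: alpha by band lookup
  cl <- classify_state(sine_rec(9, amp = 3))
  expect_equal(cl$label, "alpha")
  # flat noise with a failing retest: non-oscillatory
  weak <- sine_rec(9, amp = 0.1, noise = 0.05)
  cl <- classify_state(weak, trigger_retest = function() weak)
  expect_equal(cl$label, "non-oscillatory")
  # triggered 8 Hz train lasting ~1.3 s with power >> 3: spindle via retest
  t <- seq(0, 2.999, 1e-3)
  burst <- ifelse(t >= 1.05 & t < 2.35, 4 * sin(2 * pi * 8 * t), 0) +
    rnorm(length(t), 0, 0.02)
  trig <- synthetic_recording(burst)
  trig$params <- list(trigger = list(onset = 1000))
  cl <- classify_state(weak, trigger_retest = function() trig)
  expect_equal(cl$label, "spindle")
  # spontaneous spindle: quiet, then a 10 Hz burst, then quiet
  spont <- ifelse(t >= 1.4 & t < 2.5, 3.5 * sin(2 * pi * 10 * t), 0) +
    rnorm(length(t), 0, 0.02)
  cl <- classify_state(synthetic_recording(spont))
  expect_equal(cl$label, "spindle")
  expect_true(cl$spontaneous)
})

test_that("oscillation duration tracks band-limited activity", {
  set.seed(6)
  t <- seq(0, 3.999, 1e-3)
  x <- ifelse(t >= 1 & t < 3, 4 * sin(2 * pi * 10 * t), 0) +
    rnorm(length(t), 0, 0.02)
  rec <- synthetic_recording(x)
  dur <- oscillation_duration(rec, onset = 1000, band = c(7, 15))
  expect_gt(dur, 1600)
  expect_lt(dur, 2400)
})

test_that("entrainment profiles normalise by the baseline peak and lock", {
  t <- seq(0, 2.499, 1e-3)
  # baseline 10 Hz (amp 2) for 1.5 s, then an 11 Hz segment (amp 3)
  x <- ifelse(t < 1.5, 2 * sin(2 * pi * 10 * t), 3 * sin(2 * pi * 11 * t))
  rec <- synthetic_recording(x)
  sweep <- list(recording = rec,
                segments = data.frame(frequency = 22, start = 1500,
                                      end = 2500),
                baseline = c(200, 1500))
  prof <- entrainment_profile(sweep)
  expect_equal(prof$f_dom, 11, tolerance = 0.3)
  expect_equal(prof$lock, "2:1")
  expect_equal(prof$normalized, (3^2 / 2) / (2^2 / 2), tolerance = 0.25)
})
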