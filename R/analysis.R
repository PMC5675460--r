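## Quantitative readouts: simulated LFP, spectra, spike phases and the
## synchronization index, PETH cross-correlation, firing/burst statistics,
## oscillatory-state classification, and entrainment profiling.

#' Simulated local field potential
#'
#' The sLFP is the band-pass-filtered (default 0.5-80 Hz) average membrane
#' potential of a population set, computed after removing the settling
#' window.  Filtering uses a linear-phase FIR filter applied
#' forward-backward (zero phase).
#'
#' @param recording a `thalamic_recording`.
#' @param population "TC" (cell-count-weighted mean of HTC and RTC, the
#'   default), "HTC", "RTC", or any cell type.
#' @param band filter pass band, Hz.
#' @param order FIR filter order.
#' @param from start of the analysis window, ms (default: the recording's
#'   discard window).
#' @return object of class `slfp` with fields `t` (ms), `x` (mV), `fs` (Hz).
#' @export
compute_slfp <- function(recording, population = "TC", band = c(0.5, 80),
                         order = 300, from = NULL) {
  r <- recording
  if (is.null(from)) from <- r$discard
  keep <- r$t >= from
  if (population == "TC") {
    w <- r$sizes[c("HTC", "RTC")]
    x <- (r$mean_v[, "HTC"] * w[1] + r$mean_v[, "RTC"] * w[2]) / sum(w)
  } else {
    x <- r$mean_v[, population]
  }
  x <- x[keep]
  t <- r$t[keep]
  fs <- 1000 / r$stride_ms
  if (length(x) <= 3 * order)
    stop("trace too short for the FIR filter warm-up")
  x <- x - mean(x)
  fl <- signal::fir1(order, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(fl, x)
  structure(list(t = t, x = as.numeric(xf), fs = fs, band = band),
            class = "slfp")
}

#' One-sided power spectrum
#'
#' FFT power spectrum scaled so that a pure sinusoid of amplitude `A`
#' yields a peak of `A^2/2` (mV^2); these are the units in which the
#' classifier's power thresholds are expressed.  The signal is zero-padded
#' for a fine frequency grid.
#'
#' @param x signal (mV) or an `slfp` object.
#' @param fs sampling rate, Hz (ignored when `x` is an `slfp`).
#' @param window "rect" for long segments, "hann" for 1 s stimulation
#'   segments.
#' @param pad zero-padding factor.
#' @return data frame with `frequency` (Hz) and `power` (mV^2).
#' @export
power_spectrum <- function(x, fs = NULL, window = c("rect", "hann"), pad = 8) {
  if (inherits(x, "slfp")) { fs <- x$fs; x <- x$x }
  window <- match.arg(window)
  n <- length(x)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)) else rep(1, n)
  xw <- (x - mean(x)) * w
  nfft <- 2^ceiling(log2(n * pad))
  X <- stats::fft(c(xw, numeric(nfft - n)))
  half <- 1:(nfft / 2)
  amp <- 2 * Mod(X[half]) / sum(w)
  data.frame(frequency = (half - 1) * fs / nfft, power = amp^2 / 2)
}

#' Dominant oscillation frequency
#'
#' The peak of the power spectrum restricted to a frequency band.
#'
#' @param x signal or `slfp`.
#' @param fs sampling rate (Hz) when `x` is a bare vector.
#' @param band search band, Hz.
#' @param window passed to [power_spectrum()].
#' @return list with `frequency` (Hz) and `power` (mV^2).
#' @export
dominant_frequency <- function(x, fs = NULL, band = c(0.5, 80),
                               window = "rect") {
  ps <- power_spectrum(x, fs, window = window)
  sel <- ps$frequency >= band[1] & ps$frequency <= band[2]
  i <- which.max(ps$power[sel])
  list(frequency = ps$frequency[sel][i], power = ps$power[sel][i])
}

# local maxima above a height threshold with a minimum separation (samples)
.find_peaks <- function(x, min_height, min_dist) {
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  out <- integer(0)
  for (i in cand) {
    if (!length(out) || i - out[length(out)] >= min_dist) out <- c(out, i)
    else if (x[i] > x[out[length(out)]]) out[length(out)] <- i
  }
  out
}

#' Convert spike times to oscillation phases
#'
#' Phases are defined against the peaks of the sign-reversed sLFP: each
#' `-sLFP` peak marks phase 0 (2 pi), and a spike's phase is interpolated
#' linearly between its flanking peaks.  Spikes outside the first/last peak
#' are dropped.  Peak detection: local maxima of `-sLFP` above its 60th
#' percentile, separated by at least half the dominant period.
#'
#' @param spike_times spike times, ms.
#' @param slfp an `slfp` object.
#' @return numeric vector of phases in `[0, 2 pi)`.
#' @export
spike_phases <- function(spike_times, slfp) {
  y <- -slfp$x
  f0 <- dominant_frequency(slfp)$frequency
  min_dist <- max(1, floor(0.5 * slfp$fs / f0))
  pk <- .find_peaks(y, stats::quantile(y, 0.6), min_dist)
  if (length(pk) < 2) stop("fewer than two sLFP peaks")
  pk_t <- slfp$t[pk]
  idx <- findInterval(spike_times, pk_t)
  ok <- idx >= 1 & idx < length(pk_t)
  idx <- idx[ok]
  st <- spike_times[ok]
  2 * pi * (st - pk_t[idx]) / (pk_t[idx + 1] - pk_t[idx])
}

#' Synchronization index
#'
#' `kappa = (1/N) sqrt((sum sin(phi))^2 + (sum cos(phi))^2)`, the modulus of
#' the population's resultant phase vector; 1 when all spikes share a phase,
#' 0 for phases spread uniformly on the circle.
#'
#' @param phi spike phases, radians.
#' @return kappa in `[0, 1]`, or `NA` for an empty phase set.
#' @export
sync_index <- function(phi) {
  n <- length(phi)
  if (n == 0) return(NA_real_)
  sqrt(sum(sin(phi))^2 + sum(cos(phi))^2) / n
}

#' Synchronization index of one population of a recording
#'
#' @param recording a `thalamic_recording`.
#' @param population cell type.
#' @param slfp optional precomputed `slfp`.
#' @return kappa.
#' @export
population_sync <- function(recording, population, slfp = NULL) {
  if (is.null(slfp)) slfp <- compute_slfp(recording)
  st <- recording$spikes
  tt <- st$time[st$pop == population & st$time >= recording$discard]
  if (!length(tt)) return(NA_real_)
  sync_index(spike_phases(tt, slfp))
}

# population PETH: spike counts in 2 ms bins over the analysis window
.peth <- function(times, from, to, bin = 2) {
  nb <- floor((to - from) / bin)
  tt <- times[times >= from & times < from + nb * bin]
  tabulate(floor((tt - from) / bin) + 1L, nbins = nb)
}

#' Cross-correlation index of two spike trains
#'
#' Peri-event time histograms (2 ms bins) are mean-removed and correlated;
#' the index is the Pearson-normalised cross-correlation peak over lags up
#' to `max_lag` ms.
#'
#' @param times_a,times_b spike times (ms) of the two populations.
#' @param from,to analysis window, ms.
#' @param bin bin width, ms.
#' @param max_lag maximum lag searched, ms.
#' @return list with `peak` (correlation index in `[-1, 1]`) and `lag` (ms);
#'   `peak` is `NA` when either train is empty.
#' @export
peth_crosscorr <- function(times_a, times_b, from, to, bin = 2,
                           max_lag = 250) {
  a <- .peth(times_a, from, to, bin)
  b <- .peth(times_b, from, to, bin)
  if (sum(a) == 0 || sum(b) == 0 || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(peak = NA_real_, lag = NA_real_))
  a <- a - mean(a); b <- b - mean(b)
  L <- min(length(a) - 1, floor(max_lag / bin))
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a[1:(length(a) - k)] * b[(1 + k):length(b)])
    else sum(a[(1 - k):length(a)] * b[1:(length(b) + k)])
  }, numeric(1))
  cc <- cc / sqrt(sum(a^2) * sum(b^2))
  i <- which.max(cc)
  list(peak = cc[i], lag = lags[i] * bin)
}

#' Mean cross-correlation over the six population pairs
#'
#' @param recording a `thalamic_recording`.
#' @return list with the pairwise table and the network mean.
#' @export
network_correlation <- function(recording) {
  pops <- c("HTC", "RTC", "IN", "RE")
  prs <- utils::combn(pops, 2)
  from <- recording$discard; to <- recording$duration
  st <- recording$spikes
  vals <- apply(prs, 2, function(p) {
    peth_crosscorr(st$time[st$pop == p[1]], st$time[st$pop == p[2]],
                   from, to)$peak
  })
  data.frame(pair = paste(prs[1, ], prs[2, ], sep = "-"), index = vals) ->
    tab
  list(pairs = tab, mean = mean(vals, na.rm = TRUE))
}

#' Firing-rate and burst statistics of a spike train
#'
#' A burst is a maximal group of >= 2 spikes with intra-burst inter-spike
#' intervals <= 10 ms.
#'
#' @param spike_times spike times, ms.
#' @param from,to analysis window, ms.
#' @param isi_max intra-burst ISI bound, ms.
#' @return list: `rate` (Hz), `n_bursts`, `spikes_per_burst` (mean),
#'   `burst_freq` (Hz).
#' @export
firing_and_burst_stats <- function(spike_times, from, to, isi_max = 10) {
  tt <- sort(spike_times[spike_times >= from & spike_times < to])
  win_s <- (to - from) / 1000
  if (!length(tt))
    return(list(rate = 0, n_bursts = 0, spikes_per_burst = NA_real_,
                burst_freq = 0))
  grp <- cumsum(c(1, diff(tt) > isi_max))
  sz <- tabulate(grp)
  bursts <- sz[sz >= 2]
  list(rate = length(tt) / win_s,
       n_bursts = length(bursts),
       spikes_per_burst = if (length(bursts)) mean(bursts) else NA_real_,
       burst_freq = length(bursts) / win_s)
}

#' Population firing rates of a recording
#'
#' @param recording a `thalamic_recording`.
#' @return named vector of mean per-cell firing rates (Hz) for each type.
#' @export
population_rates <- function(recording) {
  from <- recording$discard; to <- recording$duration
  win_s <- (to - from) / 1000
  st <- recording$spikes
  out <- vapply(c(HTC = "HTC", RTC = "RTC", IN = "IN", RE = "RE"),
                function(p) sum(st$pop == p & st$time >= from & st$time < to) /
                  recording$sizes[[p]] / win_s,
                numeric(1))
  out
}

# peak power and frequency of one signal slice (hann window for 1 s slices)
.slice_peak <- function(x, fs, band = c(0.5, 80), window = "hann") {
  dominant_frequency(x, fs, band = band, window = window)
}

#' Duration of band-limited oscillatory activity
#'
#' Slides a window (default 500 ms, 100 ms step) over the sLFP starting at
#' `onset` and measures how long the spectral peak stays inside `band` with
#' power above `threshold`.
#'
#' @param recording a `thalamic_recording`.
#' @param onset start of the measurement, ms (e.g. the trigger onset).
#' @param band frequency band, Hz.
#' @param threshold power threshold (mV^2).
#' @param width,step sliding window width and step, ms.
#' @return duration in ms of the contiguous active stretch beginning at the
#'   first active window at/after `onset` (0 if none).
#' @export
oscillation_duration <- function(recording, onset = 1000, band = c(7, 15),
                                 threshold = 3, width = 500, step = 100) {
  sl <- compute_slfp(recording, from = recording$discard)
  fs <- sl$fs
  starts <- seq(onset, recording$duration - width, by = step)
  active <- vapply(starts, function(s) {
    ix <- sl$t >= s & sl$t < s + width
    pk <- .slice_peak(sl$x[ix], fs)
    pk$power > threshold && pk$frequency >= band[1] && pk$frequency <= band[2]
  }, logical(1))
  if (!any(active)) return(0)
  first <- which(active)[1]
  run_end <- first
  while (run_end < length(active) && active[run_end + 1]) run_end <- run_end + 1
  (starts[run_end] + width) - starts[first]
}

#' Classify the oscillatory state of a recording
#'
#' Implements the three-step map-classification procedure: (1) spontaneous
#' spindles - a 1 s stretch with 7-15 Hz peak power above `thr_spindle`
#' preceded by a 1 s stretch below `thr_osc`; (2) otherwise, if the final
#' 1 s of the simulation has peak power above `thr_osc`, label by the band
#' of the dominant frequency (delta 1-4, theta 4-8, alpha 8-14, beta 14-30,
#' gamma > 30 Hz); (3) otherwise run the trigger retest (a transient RE
#' input): if it evokes more than 500 ms of 7-15 Hz activity with power
#' above `thr_spindle`, label spindle, else non-oscillatory.
#'
#' @param recording a 3 s (or longer) `thalamic_recording`.
#' @param trigger_retest `NULL`, or a function of no arguments returning a
#'   `thalamic_recording` of the same condition with the spindle trigger
#'   applied (used only when steps 1-2 find no oscillation).
#' @param thr_osc,thr_spindle power thresholds (mV^2).
#' @return list with `label` (one of "delta", "theta", "alpha", "beta",
#'   "gamma", "spindle", "non-oscillatory"), `frequency`, `power`.
#' @export
classify_state <- function(recording, trigger_retest = NULL,
                           thr_osc = 1, thr_spindle = 3) {
  if (recording$duration - recording$discard < 2000)
    stop("classification needs at least 2 s of analysable signal")
  sl <- compute_slfp(recording)
  fs <- sl$fs

  ## step 1: spontaneous spindle
  starts <- seq(recording$discard + 1000, recording$duration - 1000, by = 250)
  for (s in starts) {
    ev <- .slice_peak(sl$x[sl$t >= s & sl$t < s + 1000], fs)
    if (ev$power > thr_spindle && ev$frequency >= 7 && ev$frequency <= 15) {
      pre <- .slice_peak(sl$x[sl$t >= s - 1000 & sl$t < s], fs)
      if (pre$power < thr_osc)
        return(list(label = "spindle", frequency = ev$frequency,
                    power = ev$power, spontaneous = TRUE))
    }
  }

  ## step 2: band label from the final second
  fin <- .slice_peak(sl$x[sl$t >= recording$duration - 1000], fs)
  if (fin$power > thr_osc) {
    f <- fin$frequency
    lab <- if (f <= 4) "delta" else if (f <= 8) "theta" else if (f <= 14)
      "alpha" else if (f <= 30) "beta" else "gamma"
    return(list(label = lab, frequency = f, power = fin$power,
                spontaneous = FALSE))
  }

  ## step 3: trigger retest
  if (!is.null(trigger_retest)) {
    rec2 <- trigger_retest()
    onset <- (rec2$params$trigger$onset) %||% 1000
    dur <- oscillation_duration(rec2, onset = onset, band = c(7, 15),
                                threshold = thr_spindle)
    if (dur > 500) {
      sl2 <- compute_slfp(rec2)
      ev <- .slice_peak(sl2$x[sl2$t >= onset & sl2$t < onset + 1000], sl2$fs)
      return(list(label = "spindle", frequency = ev$frequency,
                  power = ev$power, spontaneous = FALSE))
    }
  }
  list(label = "non-oscillatory", frequency = fin$frequency,
       power = fin$power, spontaneous = FALSE)
}

#' Entrainment and resonance profile of a stimulation sweep
#'
#' Computes, per stimulation-frequency segment, the dominant sLFP frequency
#' and the spectral peak normalised by the unstimulated baseline peak, and
#' detects locking ratios `k:m` (k, m in 1..3) where
#' `|m f_dom - k f_stim| <= tol`.
#'
#' @param sweep result of [run_sweep()].
#' @param tol locking tolerance, Hz.
#' @return data frame with one row per segment: `frequency` (stimulation),
#'   `f_dom`, `power`, `normalized`, `lock` (e.g. "1:1", "2:1" or "").
#' @export
entrainment_profile <- function(sweep, tol = 0.5) {
  rec <- sweep$recording
  sl <- compute_slfp(rec)
  fs <- sl$fs
  base_win <- sweep$baseline
  if (diff(base_win) < 900) stop("missing baseline window")
  bx <- sl$x[sl$t >= base_win[2] - 1000 & sl$t < base_win[2]]
  base <- .slice_peak(bx, fs)
  segs <- sweep$segments
  out <- lapply(seq_len(nrow(segs)), function(i) {
    sx <- sl$x[sl$t >= segs$start[i] & sl$t < segs$end[i]]
    pk <- .slice_peak(sx, fs)
    fst <- segs$frequency[i]
    # a k:m lock means k cycles of stimulation per m network cycles,
    # e.g. 22 Hz stimulation with an 11 Hz rhythm locks 2:1
    lock <- ""
    best <- Inf
    for (k in 1:3) for (m in 1:3) {
      err <- abs(m * pk$frequency - k * fst)
      if (err <= tol && k + m < best) { lock <- paste0(m, ":", k); best <- k + m }
    }
    data.frame(frequency = fst, f_dom = pk$frequency, power = pk$power,
               normalized = pk$power / base$power, lock = lock,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "baseline_power") <- base$power
  attr(res, "baseline_frequency") <- base$frequency
  res
}
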