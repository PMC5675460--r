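## Stimulation protocols: the spindle trigger and the periodic pulse-train
## frequency sweep applied to the LGN (TC and IN cells).

#' The spindle trigger protocol
#'
#' A transient depolarising input (default 100 ms x 100 pA) injected into
#' all RE cells, representing a cortical UP state.
#'
#' @param amplitude nA.
#' @param duration ms.
#' @param onset ms.
#' @return list accepted by the `trigger` argument of [simulate_thalamus()].
#' @export
trigger_protocol <- function(amplitude = 0.1, duration = 100, onset = 1000) {
  stopifnot(amplitude >= 0, duration > 0)
  list(pop = "RE", amplitude = amplitude, duration = duration, onset = onset)
}

#' A periodic pulse-train protocol
#'
#' A train of square current pulses (default 10 ms, 0.2 nA) applied at one
#' or several frequencies, each dwelling for a fixed time; all LGN neurons
#' (TC and IN cells) receive the identical waveform.
#'
#' @param frequencies stimulation frequencies, Hz.
#' @param amplitude pulse amplitude, nA.
#' @param width pulse width, ms.
#' @param dwell time per frequency, ms.
#' @param targets cell types receiving the stimulus.
#' @return object of class `pulse_train_protocol`.
#' @export
pulse_train_protocol <- function(frequencies = 1:50, amplitude = 0.2,
                                 width = 10, dwell = 1000,
                                 targets = c("HTC", "RTC", "IN")) {
  if (any(frequencies > 0 & 1000 / frequencies < width))
    stop("pulse width exceeds the stimulation period")
  structure(list(frequencies = frequencies, amplitude = amplitude,
                 width = width, dwell = dwell, targets = targets),
            class = "pulse_train_protocol")
}

#' Build the applied-current waveform of a pulse-train protocol
#'
#' Frequency segments are contiguous; within each segment the first pulse
#' starts at the segment onset.
#'
#' @param protocol a [pulse_train_protocol()].
#' @param duration total waveform length, ms (>= protocol span).
#' @param dt sample step, ms.
#' @param offset time of the first segment onset, ms.
#' @return list with `wave` (nA per step sample), `segments` (data frame
#'   with `frequency`, `start`, `end` in ms) and `targets`.
#' @export
build_waveform <- function(protocol, duration = NULL, dt = 0.02, offset = 0) {
  p <- protocol
  span <- offset + length(p$frequencies) * p$dwell
  if (is.null(duration)) duration <- span
  if (duration < span) stop("duration does not cover the protocol")
  n <- as.integer(round(duration / dt))
  tgrid <- (0:n) * dt
  wave <- numeric(n + 1)
  segs <- data.frame(frequency = p$frequencies,
                     start = offset + (seq_along(p$frequencies) - 1) * p$dwell,
                     end = offset + seq_along(p$frequencies) * p$dwell)
  for (i in seq_len(nrow(segs))) {
    f <- segs$frequency[i]
    if (f <= 0 || p$amplitude == 0) next
    period <- 1000 / f
    tt <- tgrid - segs$start[i]
    in_seg <- tt >= 0 & tgrid < segs$end[i]
    phase <- tt[in_seg] %% period
    wave[in_seg][phase < p$width] <- p$amplitude
  }
  list(wave = wave, segments = segs, targets = p$targets)
}

#' Run the stimulation frequency sweep on a named state
#'
#' Simulates the named oscillatory state with the pulse train applied as one
#' continuous run (contiguous 1 s segments, ascending frequency), after an
#' initial unstimulated baseline window.
#'
#' @param state "delta", "alpha" or "gamma".
#' @param seed topology/noise seed.
#' @param frequencies stimulation frequencies, Hz.
#' @param amplitude pulse amplitude, nA.
#' @param baseline unstimulated time before the first segment, ms (also
#'   serves as the settling window).
#' @param ... passed to [simulate_thalamus()].
#' @return list with the `recording`, the `segments` table and the
#'   `baseline` window `c(start, end)`.
#' @export
run_sweep <- function(state, seed = 1, frequencies = 1:50, amplitude = 0.2,
                      baseline = 1500, ...) {
  state <- match.arg(state, c("delta", "alpha", "gamma"))
  proto <- pulse_train_protocol(frequencies = frequencies,
                                amplitude = amplitude)
  duration <- baseline + length(frequencies) * proto$dwell
  wf <- build_waveform(proto, duration = duration, offset = baseline)
  rec <- run_named_state(state, seed = seed, duration = duration,
                         stimulus = list(wave = wf$wave, targets = wf$targets),
                         ...)
  list(recording = rec, segments = wf$segments,
       baseline = c(rec$discard, baseline))
}
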