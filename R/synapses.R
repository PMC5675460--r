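## Chemical synapses, short-term depression, gap junctions, Poisson drive.
##
## Chemical current: I_syn = g_syn * D * s * B(V) * (V - E_syn)  [nA]
## with s the fraction of open channels (first-order transmitter binding),
## D the short-term-depression scaling, and B(V) the magnesium block
## (NMDA only).

#' Receptor kinetic constants and pulse parameters
#'
#' Forward/backward transmitter binding rates per receptor, the transmitter
#' pulse (0.5 mM for 0.3 ms), the 2 ms axonal delay, and the short-term
#' depression constants (U = 0.07, tau = 700 ms).
#' @return named list of constants.
#' @export
synapse_constants <- function() {
  list(
    alpha = c(AMPA = 0.94, NMDA = 1.0, GABAA = 10.5),   # 1/(mM ms)
    beta  = c(AMPA = 0.18, NMDA = 0.0067, GABAA = 0.166), # 1/ms
    pulse_amp = 0.5,    # mM
    pulse_dur = 0.3,    # ms
    delay = 2,          # ms
    U = 0.07,           # depression: fraction used per spike
    tau_d = 700,        # depression recovery, ms
    tau_input = 5,      # Poisson input conductance decay, ms
    input_rate = 100    # Poisson event rate per neuron, Hz
  )
}

#' Transmitter concentration at time t
#'
#' Each presynaptic spike opens a saturating 0.5 mM pulse of duration 0.3 ms
#' starting `delay` ms after the spike; overlapping pulses form a union and
#' do not sum.
#'
#' @param spike_times sorted presynaptic spike times, ms.
#' @param t evaluation time(s), ms.
#' @param delay axonal delay, ms.
#' @param dur pulse duration, ms.
#' @param amp pulse amplitude, mM.
#' @return transmitter concentration in mM at each `t`.
#' @export
transmitter_concentration <- function(spike_times, t,
                                      delay = 2, dur = 0.3, amp = 0.5) {
  if (length(spike_times) == 0) return(rep(0, length(t)))
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  on <- vapply(t, function(ti)
    any(ti >= spike_times + delay & ti < spike_times + delay + dur), logical(1))
  amp * as.numeric(on)
}

#' One integration step of the synaptic gating variable
#'
#' `ds/dt = alpha [T] (1 - s) - beta s` advanced over `dt` with `[T]` held
#' constant, using the same fourth-order update polynomial as the membrane
#' integrator (exact to O(dt^5) for this linear equation).
#'
#' @param s open fraction in `[0, 1]`.
#' @param Tt transmitter concentration, mM.
#' @param receptor "AMPA", "NMDA" or "GABAA".
#' @param dt step, ms.
#' @return updated open fraction.
#' @export
syn_gating_step <- function(s, Tt, receptor = "AMPA", dt = 0.02) {
  stopifnot(all(s >= 0 & s <= 1))
  k <- synapse_constants()
  a <- k$alpha[[receptor]] * Tt
  lam <- a + k$beta[[receptor]]
  s_inf <- ifelse(lam > 0, a / lam, 0)
  x <- -lam * dt
  p4 <- 1 + x * (1 + x * (0.5 + x * (1 / 6 + x / 24)))
  pmin(1, pmax(0, s_inf + (s - s_inf) * p4))
}

#' NMDA magnesium block
#'
#' `B(V) = 1 / (1 + exp(-(V + 25)/12.5))`; identically 1 for AMPA and
#' GABA_A receptors.
#' @param v membrane potential, mV.
#' @return open fraction of the magnesium block in (0, 1).
#' @export
mg_block <- function(v) 1 / (1 + exp(-(v + 25) / 12.5))

#' Short-term depression state at time t
#'
#' Between presynaptic spikes the available fraction recovers as
#' `D(t) = 1 - (1 - D_i (1 - U)) exp(-(t - t_i)/tau)` where `D_i` is the
#' value immediately before the i-th spike at `t_i`.  At a spike the
#' available fraction drops to `D_i (1 - U)`.
#'
#' @param state list with `D_i` (pre-spike value at the last spike) and
#'   `t_i` (last spike time, ms; `-Inf` for none).
#' @param t current time, ms (`t >= t_i`).
#' @param is_spike if `TRUE`, register a presynaptic spike at `t` and return
#'   the updated state.
#' @param U,tau depression constants.
#' @return if `is_spike`, the updated state; otherwise the value `D(t)`.
#' @export
depression_update <- function(state, t, is_spike = FALSE,
                              U = 0.07, tau = 700) {
  if (t < state$t_i) stop("time must not run backwards")
  D_now <- if (is.infinite(state$t_i)) 1
           else 1 - (1 - state$D_i * (1 - U)) * exp(-(t - state$t_i) / tau)
  if (!is_spike) return(D_now)
  list(D_i = D_now, t_i = t)
}

#' Chemical synaptic current
#'
#' @param g_syn maximal conductance, nS.
#' @param s open fraction.
#' @param D depression scaling in (0, 1].
#' @param v_post postsynaptic potential, mV.
#' @param E_syn reversal potential, mV.
#' @param nmda if `TRUE`, apply the magnesium block [mg_block()].
#' @return current in nA (positive = outward).
#' @export
chem_current <- function(g_syn, s, D, v_post, E_syn, nmda = FALSE) {
  B <- if (nmda) mg_block(v_post) else 1
  1e-3 * g_syn * D * s * B * (v_post - E_syn)
}

#' Gap-junction current into the postsynaptic cell
#'
#' `I_gap = (V_post - V_pre) / R_g` in nA (mV / MOhm); the presynaptic cell
#' receives the opposite current, so every electrical edge conserves charge.
#'
#' @param v_pre,v_post endpoint potentials, mV.
#' @param r_g junction resistance, MOhm.
#' @return current in nA (positive = outward from the post cell).
#' @export
gap_current <- function(v_pre, v_post, r_g) {
  stopifnot(r_g > 0)
  (v_post - v_pre) / r_g
}

#' Afferent input conductance from a Poisson event train
#'
#' Each event steps the conductance up by `g_input` instantaneously; between
#' events it decays exponentially with a 5 ms time constant.  Events
#' superpose additively (shot noise).
#'
#' @param event_times event times, ms (sorted).
#' @param t evaluation time(s), ms.
#' @param g_input increment per event, nS.
#' @param tau decay time constant, ms.
#' @return conductance in nS at each `t`.
#' @export
poisson_conductance <- function(event_times, t, g_input, tau = 5) {
  vapply(t, function(ti) {
    past <- event_times[event_times <= ti]
    if (!length(past)) 0 else g_input * sum(exp(-(ti - past) / tau))
  }, numeric(1))
}

#' Draw a Poisson event train
#'
#' Homogeneous Poisson process on `[0, duration)`; uses the current R RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param rate events per second.
#' @param duration ms.
#' @return sorted event times in ms.
#' @export
poisson_events <- function(rate, duration) {
  if (rate <= 0 || duration <= 0) return(numeric(0))
  n_exp <- rate * duration / 1000
  n <- stats::rpois(1, n_exp)
  sort(stats::runif(n, 0, duration))
}

# Default pathway table: chemical connectivity of the thalamic circuit.
# Conductances in nS; E_gaba depends on the postsynaptic class (-80 mV onto
# LGN cells, -70 mV onto RE cells).  `p` is the connection probability.
.pathway_table <- function() {
  data.frame(
    pathway = c("HTC->IN", "IN->RTC", "HTC->RE", "RTC->RE",
                "RE->HTC", "RE->RTC", "RE->RE", "RE->IN"),
    pre  = c("HTC", "IN", "HTC", "RTC", "RE", "RE", "RE", "RE"),
    post = c("IN", "RTC", "RE", "RE", "HTC", "RTC", "RE", "IN"),
    p    = c(0.3, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2, 0.05),
    g_ampa = c(6, 0, 4, 4, 0, 0, 0, 0),
    g_nmda = c(3, 0, 2, 2, 0, 0, 0, 0),
    g_gaba = c(0, 3, 0, 0, 3, 3, 1, 1),
    E_gaba = c(NA, -80, NA, NA, -80, -80, -70, -80),
    stringsAsFactors = FALSE
  )
}
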