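## Gating-variable kinetics for all voltage-gated channels.
##
## Every gating variable x follows the first-order scheme
##   dx/dt = phi_x * (x_inf(V, Ca) - x) / tau_x(V, Ca)
## or, equivalently in rate form,
##   dx/dt = phi_x * (alpha_x (1 - x) - beta_x x).
## Units: V in mV, Ca in uM, tau in ms, rates in 1/ms.

# Guarded evaluation of x/(exp(x/k) - 1), the Traub-style rate expression,
# which has a removable singularity at x = 0.
.expm1_rate <- function(x, k) {
  out <- ifelse(abs(x) < 1e-6, k - x / 2, x / expm1(x / k))
  out
}

#' Describe the kinetics of one gating variable
#'
#' A gating spec bundles either steady-state/time-constant functions
#' `x_inf(V, Ca)` and `tau(V, Ca)` or forward/backward rate functions
#' `alpha(V, Ca)` and `beta(V, Ca)`, together with the temperature factor
#' `phi` and an optional voltage `shift` (used to derive the high-threshold
#' T-type current from the low-threshold one).
#'
#' @param name label for the variable (e.g. "T_m").
#' @param x_inf,tau functions of `(v, ca)` returning steady state and time
#'   constant (ms); supply these *or* `alpha`/`beta`.
#' @param alpha,beta rate functions of `(v, ca)` in 1/ms.
#' @param phi dimensionless temperature factor multiplying dx/dt.
#' @param shift voltage offset in mV: kinetics are evaluated at `v - shift`.
#' @return an object of class `gating_spec`.
#' @export
gating_spec <- function(name, x_inf = NULL, tau = NULL,
                        alpha = NULL, beta = NULL, phi = 1, shift = 0) {
  rate_form <- !is.null(alpha)
  if (rate_form && (is.null(beta)))
    stop("rate-form gating spec needs both alpha and beta")
  if (!rate_form && (is.null(x_inf) || is.null(tau)))
    stop("gating spec needs either x_inf/tau or alpha/beta")
  structure(list(name = name, x_inf = x_inf, tau = tau,
                 alpha = alpha, beta = beta, phi = phi, shift = shift,
                 rate_form = rate_form),
            class = "gating_spec")
}

#' Evaluate a gating spec
#'
#' Returns the steady state and time constant at a given voltage and
#' intracellular calcium.  For rate-form specs these are `alpha/(alpha+beta)`
#' and `1/(alpha+beta)`.
#'
#' @param spec a [gating_spec()].
#' @param v membrane potential, mV.
#' @param ca intracellular calcium, uM.
#' @return list with elements `x_inf` and `tau` (ms).
#' @export
eval_gating <- function(spec, v, ca = .const$ca_rest) {
  stopifnot(inherits(spec, "gating_spec"))
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  if (any(!is.finite(ca)) || any(ca <= 0)) stop("calcium must be finite and > 0")
  vs <- v - spec$shift
  if (spec$rate_form) {
    a <- spec$alpha(vs, ca)
    b <- spec$beta(vs, ca)
    list(x_inf = a / (a + b), tau = 1 / (a + b))
  } else {
    list(x_inf = spec$x_inf(vs, ca), tau = spec$tau(vs, ca))
  }
}

## ---- transient sodium / delayed-rectifier potassium (Traub-type) ----
## vtr shifts the kinetics so that the spike threshold sits near -50 mV.

kin_na_m <- function(vtr = -50) gating_spec(
  "Na_m",
  alpha = function(v, ca) 0.32 * .expm1_rate(13 - (v - vtr), 4),
  beta  = function(v, ca) 0.28 * .expm1_rate((v - vtr) - 40, 5))

kin_na_h <- function(vtr = -65) gating_spec(
  "Na_h",
  alpha = function(v, ca) 0.128 * exp((17 - (v - vtr)) / 18),
  beta  = function(v, ca) 4 / (1 + exp((40 - (v - vtr)) / 5)))

kin_dr_n <- function(vtr = -60) gating_spec(
  "DR_n",
  alpha = function(v, ca) 0.032 * .expm1_rate(15 - (v - vtr), 5),
  beta  = function(v, ca) 0.5 * exp((10 - (v - vtr)) / 40))

## ---- low-threshold T-type calcium current of TC cells ----
## Steady states and (24 C) time constants after McCormick & Huguenard's
## relay-neuron model; temperature factors bring them to 36 C.
## The high-threshold variant uses the same functions shifted by +28 mV.

kin_tc_t_m <- function(shift = 0) gating_spec(
  "T_m", shift = shift, phi = 3.55,
  x_inf = function(v, ca) 1 / (1 + exp(-(v + 57) / 6.2)),
  tau   = function(v, ca) 0.612 + 1 / (exp(-(v + 132) / 16.7) + exp((v + 16.8) / 18.2)))

kin_tc_t_h <- function(shift = 0) gating_spec(
  "T_h", shift = shift, phi = 3.0,
  x_inf = function(v, ca) 1 / (1 + exp((v + 81) / 4.0)),
  tau   = function(v, ca) ifelse(v < -80,
                                 exp((v + 467) / 66.6),
                                 28 + exp(-(v + 22) / 10.5)))

## ---- T-type calcium current of RE cells (reticular kinetics) ----

kin_re_t_m <- function() gating_spec(
  "Ts_m", phi = 5^1.2,
  x_inf = function(v, ca) 1 / (1 + exp(-(v + 52) / 7.4)),
  tau   = function(v, ca) 3 + 1 / (exp((v + 27) / 10) + exp(-(v + 102) / 15)))

kin_re_t_h <- function() gating_spec(
  "Ts_h", phi = 3^1.2,
  x_inf = function(v, ca) 1 / (1 + exp((v + 80) / 5)),
  tau   = function(v, ca) 85 + 1 / (exp((v + 48) / 4) + exp(-(v + 407) / 50)))

## ---- hyperpolarization-activated cation current ----

kin_h_m <- function() gating_spec(
  "H_m",
  x_inf = function(v, ca) 1 / (1 + exp((v + 75) / 5.5)),
  tau   = function(v, ca) 1 / (exp(-14.59 - 0.086 * v) + exp(-1.87 + 0.0701 * v)))

## ---- high-voltage-activated L-type calcium current ----

kin_l_m <- function() gating_spec(
  "L_m",
  alpha = function(v, ca) 1.6 / (1 + exp(-0.072 * (v - 5))),
  beta  = function(v, ca) 0.02 * .expm1_rate(v - 1.31, 5.36))

## ---- calcium-activated nonselective cation current (activation gate) ----

kin_can_m <- function() gating_spec(
  "CAN_m",
  x_inf = function(v, ca) 1 / (1 + exp(-(v + 43) / 5.2)),
  tau   = function(v, ca) 1.6 + 2.7 / (exp(-(v + 55) / 15) + exp((v + 55) / 15)))

## ---- calcium-dependent potassium current (rates depend on Ca only) ----
## alpha = 0.02 [Ca] (Ca in uM), beta = 0.1 (1/ms): activates within a few
## ms of a calcium burst and relaxes within ~10 ms once the shell clears,
## spacing spikes without creating deep slow after-hyperpolarizations.

kin_ahp_m <- function() gating_spec(
  "AHP_m",
  alpha = function(v, ca) 0.02 * ca + 0 * v,
  beta  = function(v, ca) rep_len(0.1, length(v)))

#' Tabulate voltage-dependent gating kinetics for the engine
#'
#' The simulation engine advances gating variables from lookup tables of
#' `A(V) = phi/tau(V)` and `B(V) = phi * x_inf(V)/tau(V)` so that
#' `dx/dt = B - A x`.  Tables are built on a uniform voltage grid and
#' linearly interpolated at run time.
#'
#' @param specs list of [gating_spec()] objects (voltage-dependent only).
#' @param v_min,v_max,dv grid range and spacing in mV.
#' @return list with the grid description and matrices `A`, `B`, `X`
#'   (steady state, used for initialisation), one column per spec.
#' @export
gating_tables <- function(specs, v_min = -130, v_max = 60, dv = 0.05) {
  v <- seq(v_min, v_max, by = dv)
  A <- B <- X <- matrix(0, length(v), length(specs))
  for (j in seq_along(specs)) {
    g <- eval_gating(specs[[j]], v)
    phi <- specs[[j]]$phi
    A[, j] <- phi / g$tau
    B[, j] <- phi * g$x_inf / g$tau
    X[, j] <- g$x_inf
  }
  list(v_min = v_min, dv = dv, n = length(v), A = A, B = B, X = X,
       names = vapply(specs, function(s) s$name, ""))
}
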