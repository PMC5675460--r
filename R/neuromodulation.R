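## The two control axes of the model: the ACh/NE modulation level, acting on
## potassium leak conductances, and the afferent drive (Poisson input
## conductance) per cell type.

# Named physiological states: potassium leak (mS/cm2) and afferent input
# conductance (nS) per cell type.
.named_states <- list(
  delta   = list(level = "low",    g_KL = c(HTC = 0.035, RTC = 0.035, IN = 0.010, RE = 0.030),
                 g_input = c(HTC = 0.1, RTC = 0.1, IN = 0.1, RE = 0.1)),
  spindle = list(level = "medium", g_KL = c(HTC = 0.010, RTC = 0.010, IN = 0.015, RE = 0.020),
                 g_input = c(HTC = 0.3, RTC = 0.3, IN = 0.3, RE = 0.3)),
  alpha   = list(level = "high",   g_KL = c(HTC = 0.000, RTC = 0.000, IN = 0.020, RE = 0.010),
                 g_input = c(HTC = 1.5, RTC = 1.5, IN = 1.5, RE = 1.5)),
  gamma   = list(level = "high",   g_KL = c(HTC = 0.000, RTC = 0.000, IN = 0.020, RE = 0.010),
                 g_input = c(HTC = 17, RTC = 17, IN = 1.5, RE = 1.5))
)

#' Parameters of a named oscillatory state
#'
#' Returns the potassium-leak conductances and afferent input conductances
#' that define the four physiological network conditions: `delta` (deep
#' sleep, low ACh/NE), `spindle` (light sleep, medium ACh/NE), `alpha`
#' (awake, eyes closed) and `gamma` (awake, attentive).
#'
#' @param name one of "delta", "spindle", "alpha", "gamma".
#' @return list with `name`, `level`, `g_KL` (mS/cm2, per cell type) and
#'   `g_input` (nS, per cell type).
#' @export
params_for_named_state <- function(name) {
  name <- match.arg(name, names(.named_states))
  c(list(name = name), .named_states[[name]])
}

# Interpolation endpoints of the transition map.  The 0% endpoint uses a
# slightly larger TC potassium leak (0.036) than the named deep-sleep state.
.map_endpoints <- list(
  lo = c(HTC = 0.036, RTC = 0.036, IN = 0.010, RE = 0.030),
  hi = c(HTC = 0.000, RTC = 0.000, IN = 0.020, RE = 0.010)
)

#' Potassium-leak conductances at an intermediate ACh/NE level
#'
#' Linear interpolation between the 0% (deep sleep) and 100% (awake)
#' endpoints per cell type; the TC and RE conductances fall with increasing
#' modulation while the IN conductance rises.
#'
#' @param lambda ACh/NE level in `[0, 1]`.
#' @return named vector of g_KL (mS/cm2) for HTC, RTC, IN, RE.
#' @export
gkl_interpolate <- function(lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("ACh/NE level must lie in [0, 1]")
  (1 - lambda) * .map_endpoints$lo + lambda * .map_endpoints$hi
}

#' The transition-map parameter grid
#'
#' 11 ACh/NE levels (0 to 1 in steps of 0.1) crossed with 41 afferent input
#' conductances (0 to 20 nS in steps of 0.5), i.e. 451 combinations.  In map
#' mode only TC cells receive Poisson input.
#'
#' @return data frame with columns `lambda` and `g_input`.
#' @export
map_grid <- function() {
  expand.grid(lambda = seq(0, 1, by = 0.1),
              g_input = seq(0, 20, by = 0.5))[, c("lambda", "g_input")]
}

#' Drive vector for map-mode runs
#'
#' @param g_input input conductance to TC cells, nS.
#' @return named per-type input conductance with IN and RE set to zero.
#' @export
map_drive <- function(g_input) {
  c(HTC = g_input, RTC = g_input, IN = 0, RE = 0)
}
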