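## Single-compartment Hodgkin-Huxley models of the four thalamic cell types.
##
## Membrane equation (C_m = 1 uF/cm2):
##   C_m dV/dt = -g_L (V - E_L) - g_KL (V - E_KL) - sum(I_int)
##               - 1e-3 * sum(I_syn)/A + 1e-3 * I_app/A
## with intrinsic currents in uA/cm2 and synaptic/applied currents in nA.

.cell_types <- c("HTC", "RTC", "IN", "RE")

# Fixed reversal potentials (mV); E_Ca is dynamic (Nernst).
.reversals <- list(Na = 50, K = -90, H = -43, CAN = 10)

#' Calcium reversal potential by the Nernst equation
#'
#' `E_Ca = (RT / 2F) ln([Ca]_o / [Ca]_i)` with the natural logarithm,
#' `T = 309.15 K` and `[Ca]_o = 2 mM`.  At the resting concentration of
#' 0.05 uM this gives about +141 mV.
#'
#' @param ca_i intracellular calcium, uM.
#' @return reversal potential in mV.
#' @export
nernst_eca <- function(ca_i) {
  if (any(!is.finite(ca_i)) || any(ca_i <= 0))
    stop("intracellular calcium must be finite and > 0")
  .nernst_slope() * log(.const$ca_out / ca_i)
}

#' Describe one ionic current
#'
#' @param name channel label (Na, DR, CaT, CaHT, CaL, H, AHP, CAN).
#' @param g maximal conductance density, mS/cm2.
#' @param E fixed reversal potential in mV, or `NA` for the dynamic calcium
#'   Nernst potential.
#' @param p,q integer exponents of the activation and inactivation gates.
#' @param m,h gating specs ([gating_spec()]); `h = NULL` when the channel
#'   does not inactivate.
#' @param michaelis if `TRUE` the open fraction is additionally scaled by the
#'   Michaelis-Menten factor `M(Ca) = Ca/(0.2 + Ca)` (Ca in uM), as for the
#'   calcium-activated nonselective cation current.
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(name, g, E, p, q = 0, m, h = NULL, michaelis = FALSE) {
  stopifnot(g >= 0)
  structure(list(name = name, g = g, E = E, p = p, q = q, m = m, h = h,
                 michaelis = michaelis),
            class = "channel_spec")
}

# Default maximal conductance densities (mS/cm2) per cell type.  These were
# calibrated so that each isolated model cell reproduces the firing modes of
# its biological counterpart across the three neuromodulatory states
# (spontaneous low-threshold bursting near the delta band at low ACh/NE,
# rebound bursts at medium levels, high-threshold bursting / tonic firing at
# high levels).
.default_densities <- function() {
  list(
    HTC = c(Na = 90, DR = 6, CaT = 2.6, CaHT = 3.0, CaL = 0.3,
            H = 0.05, AHP = 0.6, CAN = 0.05),
    RTC = c(Na = 90, DR = 6, CaT = 2.4, CaHT = 0.6, CaL = 0.3,
            H = 0.05, AHP = 0.6, CAN = 0.02),
    IN  = c(Na = 90, DR = 6, H = 0.015, CaHT = 2.5, AHP = 0.2, CAN = 0.05),
    RE  = c(Na = 100, DR = 8, CaT = 3.5, AHP = 0.05, CAN = 0.05)
  )
}

# Build the channel list for one cell type, with optional density overrides
# (a named numeric vector, e.g. c(CaHT = 4.5)).
channels_for <- function(type, densities = NULL) {
  type <- match.arg(type, .cell_types)
  g <- .default_densities()[[type]]
  if (!is.null(densities)) {
    bad <- setdiff(names(densities), names(g))
    if (length(bad)) stop("unknown channel for ", type, ": ",
                          paste(bad, collapse = ", "))
    g[names(densities)] <- densities
  }
  vtr_na <- -50
  mk <- function(nm) {
    switch(nm,
      Na   = channel_spec("Na", g[["Na"]], .reversals$Na, 3, 1,
                          kin_na_m(vtr_na), kin_na_h(vtr_na)),
      DR   = channel_spec("DR", g[["DR"]], .reversals$K, 4, 0, kin_dr_n()),
      CaT  = if (type == "RE")
               channel_spec("CaT", g[["CaT"]], NA, 2, 1,
                            kin_re_t_m(), kin_re_t_h())
             else
               channel_spec("CaT", g[["CaT"]], NA, 2, 1,
                            kin_tc_t_m(), kin_tc_t_h()),
      CaHT = channel_spec("CaHT", g[["CaHT"]], NA, 2, 1,
                          kin_tc_t_m(shift = 28), kin_tc_t_h(shift = 28)),
      CaL  = channel_spec("CaL", g[["CaL"]], NA, 2, 0, kin_l_m()),
      H    = channel_spec("H", g[["H"]], .reversals$H, 1, 0, kin_h_m()),
      AHP  = channel_spec("AHP", g[["AHP"]], .reversals$K, 2, 0, kin_ahp_m()),
      CAN  = channel_spec("CAN", g[["CAN"]], .reversals$CAN, 1, 0,
                          kin_can_m(), michaelis = TRUE))
  }
  lapply(names(g), mk)
}

#' Passive and structural parameters of one thalamic cell type
#'
#' @param type one of "HTC", "RTC", "IN", "RE".
#' @param g_KL potassium leak conductance (mS/cm2), the neuromodulated
#'   parameter; defaults to the deep-sleep value for the type.
#' @param g_L leak conductance (mS/cm2); the network draws it per cell from
#'   a uniform distribution within +/-25% of 0.01.
#' @param densities named vector of channel-density overrides (mS/cm2).
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(type, g_KL = NULL, g_L = 0.01, densities = NULL) {
  type <- match.arg(type, .cell_types)
  if (is.null(g_KL))
    g_KL <- params_for_named_state("delta")$g_KL[[type]]
  stopifnot(g_KL >= 0, g_L > 0)
  area <- switch(type, HTC = 2.9e-4, RTC = 2.9e-4, IN = 1.7e-4, RE = 1.43e-4)
  structure(list(
    type = type, C_m = 1, g_L = g_L,
    E_L = if (type %in% c("HTC", "RTC")) -70 else -60,
    g_KL = g_KL, E_KL = -90, area = area,
    tau_ca = if (type == "RE") 100 else 10,
    ca_rest = .const$ca_rest,
    channels = channels_for(type, densities)),
    class = "cell_params")
}

#' Current density through one channel
#'
#' `I = g m^p h^q (V - E)` in uA/cm2, with `E` the dynamic calcium Nernst
#' potential for Ca channels and the additional Michaelis-Menten scaling
#' `M(Ca) = Ca/(0.2 + Ca)` for the CAN current.  Positive current is outward.
#'
#' @param spec a [channel_spec()].
#' @param v membrane potential, mV.
#' @param m,h gating values in `[0, 1]`.
#' @param ca intracellular calcium, uM.
#' @return current density in uA/cm2.
#' @export
channel_current <- function(spec, v, m, h = 1, ca = .const$ca_rest) {
  stopifnot(inherits(spec, "channel_spec"))
  if (any(m < 0 | m > 1) || any(h < 0 | h > 1))
    stop("gating values must lie in [0, 1]")
  E <- if (is.na(spec$E)) nernst_eca(ca) else spec$E
  open <- m^spec$p * (if (spec$q > 0) h^spec$q else 1)
  if (spec$michaelis) open <- open * ca / (0.2 + ca)
  spec$g * open * (v - E)
}

#' Rate of change of shell calcium
#'
#' `d[Ca]/dt = -I_Ca/(zFw) + ([Ca]_rest - [Ca])/tau_Ca` with the influx term
#' converted so that a current density in uA/cm2 across a 0.5 um shell gives
#' uM/ms.
#'
#' @param i_ca total calcium current density, uA/cm2 (negative = inward).
#' @param ca_i intracellular calcium, uM.
#' @param params a [cell_params()].
#' @return derivative in uM/ms.
#' @export
calcium_derivative <- function(i_ca, ca_i, params) {
  -i_ca * .ca_influx_factor() + (params$ca_rest - ca_i) / params$tau_ca
}

#' Membrane potential derivative
#'
#' Implements the current-balance equation, including the `1e-3/A`
#' normalisation that converts synaptic and applied currents from nA to
#' uA/cm2.
#'
#' @param v membrane potential, mV.
#' @param gates named list mapping channel name to `list(m =, h =)` values;
#'   channels absent from the list are treated as closed.
#' @param ca intracellular calcium, uM.
#' @param params a [cell_params()].
#' @param i_syn total synaptic (chemical + electrical) current, nA,
#'   positive = outward.
#' @param i_app applied current, nA, positive = depolarising.
#' @return dV/dt in mV/ms.
#' @export
membrane_derivative <- function(v, gates, ca, params, i_syn = 0, i_app = 0) {
  i_int <- 0
  for (ch in params$channels) {
    gx <- gates[[ch$name]]
    if (is.null(gx)) next
    i_int <- i_int + channel_current(ch, v, gx$m, if (is.null(gx$h)) 1 else gx$h, ca)
  }
  (-params$g_L * (v - params$E_L) - params$g_KL * (v - params$E_KL) - i_int -
     1e-3 * i_syn / params$area + 1e-3 * i_app / params$area) / params$C_m
}

#' Two-leak resting potential
#'
#' Fixed point of the passive membrane with all active channels and synapses
#' off: `V = (g_L E_L + g_KL E_KL) / (g_L + g_KL)`.
#' @param params a [cell_params()].
#' @return voltage in mV.
#' @export
leak_fixed_point <- function(params) {
  (params$g_L * params$E_L + params$g_KL * params$E_KL) / (params$g_L + params$g_KL)
}

#' Read a cell-type parameter file
#'
#' The package ships one structured-text (YAML) file per cell type under
#' `extdata/cells/` carrying the passive constants and maximal conductance
#' densities.  This reads one and returns the corresponding
#' [cell_params()], allowing edited copies to define custom cells.
#'
#' @param type cell type, used to locate the shipped file when `file` is
#'   not given.
#' @param file path to a parameter file overriding the shipped one.
#' @param g_KL potassium leak conductance, mS/cm2.
#' @return a [cell_params()] object.
#' @export
read_cell_params <- function(type = c("HTC", "RTC", "IN", "RE"), file = NULL,
                             g_KL = NULL) {
  type <- match.arg(type)
  if (is.null(file))
    file <- system.file("extdata", "cells", paste0(type, ".yaml"),
                        package = "thalamosim")
  spec <- yaml::read_yaml(file)
  cell_params(spec$type, g_KL = g_KL,
              densities = unlist(spec$densities_mS_cm2))
}
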