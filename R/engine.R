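## Simulation front end: assembles engine inputs, drives the compiled RK4
## core, and wraps results in a `thalamic_recording` object.

.pop_order <- c("HTC", "RTC", "IN", "RE")

# Build gating tables + per-population channel encodings for the engine.
.engine_pops <- function(network, g_KL, densities = NULL) {
  specs <- list()
  pops <- vector("list", 4)
  for (p in seq_along(.pop_order)) {
    type <- .pop_order[p]
    ch <- channels_for(type, densities[[type]])
    n <- network$sizes[[type]]
    ch_g <- ch_E <- numeric(length(ch))
    ch_p <- ch_q <- ch_mkind <- ch_mtab <- ch_htab <- ch_can <- integer(length(ch))
    for (c in seq_along(ch)) {
      s <- ch[[c]]
      ch_g[c] <- s$g
      ch_E[c] <- if (is.na(s$E)) NA_real_ else s$E
      ch_p[c] <- s$p; ch_q[c] <- s$q
      ch_can[c] <- as.integer(s$michaelis)
      if (s$name == "AHP") {
        ch_mkind[c] <- 1L; ch_mtab[c] <- -1L
      } else {
        specs[[length(specs) + 1]] <- s$m
        ch_mtab[c] <- length(specs) - 1L
      }
      if (s$q > 0 && !is.null(s$h)) {
        specs[[length(specs) + 1]] <- s$h
        ch_htab[c] <- length(specs) - 1L
      } else ch_htab[c] <- -1L
    }
    dummy <- cell_params(type, g_KL = g_KL[[type]])
    pops[[p]] <- list(
      n = as.integer(n), area = dummy$area, g_KL = g_KL[[type]],
      E_L = dummy$E_L, E_KL = dummy$E_KL, tau_ca = dummy$tau_ca,
      ca_rest = dummy$ca_rest, g_L = network$g_L[[type]],
      ch_g = ch_g, ch_E = ch_E, ch_p = ch_p, ch_q = ch_q,
      ch_mkind = ch_mkind, ch_mtab = ch_mtab, ch_htab = ch_htab,
      ch_can = ch_can)
  }
  tab <- gating_tables(specs)
  list(pops = pops, tables = tab)
}

# Pathway list for the engine: group edge rows that share pathway-level
# attributes, convert to 0-based local indices.
.engine_chem <- function(chem) {
  if (is.null(chem) || nrow(chem) == 0) return(list())
  key <- paste(chem$pathway, chem$g_ampa, chem$g_nmda, chem$g_gaba, chem$std)
  lapply(split(seq_len(nrow(chem)), key), function(ix) {
    e <- chem[ix, ]
    list(pre_pop = match(e$pre_pop[1], .pop_order) - 1L,
         post_pop = match(e$post_pop[1], .pop_order) - 1L,
         pre = as.integer(e$pre - 1L), post = as.integer(e$post - 1L),
         g_ampa = e$g_ampa[1], g_nmda = e$g_nmda[1], g_gaba = e$g_gaba[1],
         E_gaba = if (is.na(e$E_gaba[1])) 0 else e$E_gaba[1],
         std = isTRUE(e$std[1]))
  })
}

.engine_gap <- function(gap, sizes) {
  offs <- c(0, cumsum(sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  if (is.null(gap) || nrow(gap) == 0)
    return(list(a = integer(0), b = integer(0), R = numeric(0)))
  list(a = as.integer(offs[gap$pop_a] + gap$a - 1L),
       b = as.integer(offs[gap$pop_b] + gap$b - 1L),
       R = as.numeric(gap$R_g))
}

# Independent Poisson event trains for every cell, quantized to steps.
.engine_drive <- function(sizes, g_input, rate, duration, dt) {
  offs <- c(0, cumsum(sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  N <- sum(sizes)
  g_inc <- numeric(N)
  steps <- cells <- list()
  for (type in names(sizes)) {
    gi <- g_input[[type]]
    n <- sizes[[type]]
    if (n == 0) next
    g_inc[offs[[type]] + seq_len(n)] <- gi
    if (gi <= 0 || rate <= 0) next
    for (i in seq_len(n)) {
      ev <- poisson_events(rate, duration)
      if (length(ev)) {
        steps[[length(steps) + 1]] <- as.integer(ev / dt)
        cells[[length(cells) + 1]] <- rep.int(offs[[type]] + i - 1L, length(ev))
      }
    }
  }
  st <- unlist(steps, use.names = FALSE)
  cl <- unlist(cells, use.names = FALSE)
  if (is.null(st)) { st <- integer(0); cl <- integer(0) }
  o <- order(st)
  list(ev_step = as.integer(st[o]), ev_cell = as.integer(cl[o]), g_inc = g_inc)
}

#' Simulate the thalamic network
#'
#' Integrates the full conductance-based network with the fourth-order
#' Runge-Kutta method at a fixed step (default 0.02 ms).  All randomness
#' (afferent Poisson trains) derives from `seed`; together with the network
#' graph this makes runs exactly reproducible.
#'
#' @param network a [build_network()] graph.
#' @param g_KL named per-type potassium leak conductances (mS/cm2), e.g.
#'   from [params_for_named_state()] or [gkl_interpolate()].
#' @param g_input named per-type afferent input conductances (nS).
#' @param duration total simulated time, ms.
#' @param dt integration step, ms.
#' @param discard settling window excluded from analysis, ms.
#' @param seed integer seed for the afferent noise streams.
#' @param trigger `NULL`, `TRUE` for the standard spindle trigger (100 ms x
#'   100 pA into all RE cells at t = 1000 ms), or a list with fields
#'   `amplitude` (nA), `onset`, `duration` (ms), `pop`.
#' @param stimulus `NULL` or a list with `wave` (applied current per step,
#'   nA) and `targets` (character vector of cell types).
#' @param densities per-type channel density overrides, e.g.
#'   `list(HTC = c(CaHT = 4.5))`.
#' @param input_rate afferent Poisson rate per neuron, Hz.
#' @param stride_ms recording interval for population-mean voltages, ms.
#' @param traces optional data frame with columns `pop`, `cell` selecting
#'   membrane traces to record.
#' @param check if `TRUE`, track gating/calcium bounds for invariant tests.
#' @return an object of class `thalamic_recording`.
#' @export
simulate_thalamus <- function(network, g_KL, g_input,
                              duration = 3000, dt = 0.02, discard = 500,
                              seed = 1, trigger = NULL, stimulus = NULL,
                              densities = NULL, input_rate = 100,
                              stride_ms = 1, traces = NULL, check = FALSE) {
  stopifnot(inherits(network, "thalamic_network"))
  if (duration > 0 && duration <= discard)
    stop("duration must exceed the discard window")
  n_steps <- as.integer(round(duration / dt))
  stride <- max(1L, as.integer(round(stride_ms / dt)))

  ep <- .engine_pops(network, g_KL, densities)
  chem <- .engine_chem(network$chem)
  gap <- .engine_gap(network$gap, network$sizes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  drive <- .engine_drive(network$sizes, g_input, input_rate, duration, dt)

  k <- synapse_constants()
  syn <- list(U = k$U, tau_d = k$tau_d,
              delay_steps = as.integer(round(k$delay / dt)),
              pulse_steps = as.integer(round(k$pulse_dur / dt)),
              pulse_amp = k$pulse_amp,
              alpha_ampa = k$alpha[["AMPA"]], beta_ampa = k$beta[["AMPA"]],
              alpha_nmda = k$alpha[["NMDA"]], beta_nmda = k$beta[["NMDA"]],
              alpha_gaba = k$alpha[["GABAA"]], beta_gaba = k$beta[["GABAA"]],
              tau_input = k$tau_input)

  if (isTRUE(trigger)) trigger <- list()
  trig <- if (is.null(trigger)) list(pop = -1L, amp = 0, on = 0, off = 0)
  else list(pop = match(trigger$pop %||% "RE", .pop_order) - 1L,
            amp = trigger$amplitude %||% 0.1,
            on = trigger$onset %||% 1000,
            off = (trigger$onset %||% 1000) + (trigger$duration %||% 100))

  stim <- list(wave = numeric(0), pop_mask = integer(4),
               trigger_pop = trig$pop, trigger_amp = trig$amp,
               trigger_on = trig$on, trigger_off = trig$off)
  if (!is.null(stimulus)) {
    stim$wave <- as.numeric(stimulus$wave)
    stim$pop_mask <- as.integer(.pop_order %in% stimulus$targets)
  }

  offs <- c(0, cumsum(network$sizes))[seq_along(network$sizes)]
  names(offs) <- names(network$sizes)
  trace_ids <- integer(0)
  if (!is.null(traces))
    trace_ids <- as.integer(offs[as.character(traces$pop)] + traces$cell - 1L)

  cfg <- list(dt = dt, n_steps = n_steps, stride = stride,
              trace_ids = trace_ids, check = check)

  out <- .run_network_cpp(ep$pops, ep$tables, chem, gap, syn, drive, stim, cfg)

  pop_idx <- findInterval(out$spike_id, c(0, cumsum(network$sizes)))
  spikes <- data.frame(pop = .pop_order[pop_idx],
                       cell = out$spike_id - unname(offs)[pop_idx] + 1L,
                       time = out$spike_t, stringsAsFactors = FALSE)
  mean_v <- out$mean_v
  colnames(mean_v) <- .pop_order
  iapp <- out$iapp
  colnames(iapp) <- .pop_order

  structure(list(
    spikes = spikes, t = out$t_rec, mean_v = mean_v, iapp = iapp,
    traces = out$traces, trace_select = traces,
    sizes = network$sizes, dt = dt, stride_ms = stride_ms,
    duration = duration, discard = discard, seed = seed,
    params = list(g_KL = g_KL, g_input = g_input, densities = densities,
                  trigger = trigger, stimulus_targets = stimulus$targets),
    diag = out$diag),
    class = "thalamic_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one of the four named oscillatory states
#'
#' Applies the parameters of [params_for_named_state()]; the spindle state
#' automatically receives the transient RE trigger (100 ms x 100 pA at
#' t = 1000 ms).
#'
#' @param name "delta", "spindle", "alpha" or "gamma".
#' @param seed seed used for both topology and noise streams.
#' @param network optional prebuilt network (defaults to a fresh full-size
#'   graph built from `seed`).
#' @param ... further arguments passed to [simulate_thalamus()].
#' @return a `thalamic_recording`.
#' @export
run_named_state <- function(name, seed = 1, network = NULL, ...) {
  st <- params_for_named_state(name)
  if (is.null(network)) network <- build_network(seed = seed)
  args <- list(...)
  if (identical(st$name, "spindle") && is.null(args$trigger))
    args$trigger <- TRUE
  do.call(simulate_thalamus,
          c(list(network = network, g_KL = st$g_KL, g_input = st$g_input,
                 seed = seed), args))
}

#' Current-clamp protocol on an isolated model cell
#'
#' Simulates a single cell of the given type with no synaptic inputs and no
#' afferent noise, applying a set of square current steps, and returns the
#' voltage trace.  Used to verify the firing mode of each cell type in each
#' neuromodulatory state.
#'
#' @param type cell type ("HTC", "RTC", "IN", "RE").
#' @param steps data frame with columns `amplitude` (nA), `onset`, `offset`
#'   (ms); may be empty for a free run.
#' @param duration ms.
#' @param g_KL potassium leak conductance, mS/cm2.
#' @param g_L leak conductance (default 0.01, no heterogeneity).
#' @param densities channel density overrides for this cell.
#' @param dt integration step, ms.
#' @return list with `t`, `v` (the trace, sampled every 0.1 ms), and
#'   `spikes` (spike times, ms).
#' @export
current_clamp <- function(type, steps = NULL, duration = 2000,
                          g_KL = 0.035, g_L = 0.01, densities = NULL,
                          dt = 0.02) {
  type <- match.arg(type, .pop_order)
  sizes <- c(HTC = 0, RTC = 0, IN = 0, RE = 0)
  sizes[type] <- 1
  net <- build_network(seed = 1, sizes = sizes,
                       rules = list(chem = .pathway_table()[0, ],
                                    gap = connectivity_rules()$gap[0, ]),
                       heterogeneity = FALSE)
  net$g_L[[type]] <- g_L
  n_steps <- as.integer(round(duration / dt))
  wave <- numeric(n_steps + 1)
  if (!is.null(steps) && nrow(steps) > 0) {
    tgrid <- (0:n_steps) * dt
    for (i in seq_len(nrow(steps)))
      wave[tgrid >= steps$onset[i] & tgrid < steps$offset[i]] <-
        wave[tgrid >= steps$onset[i] & tgrid < steps$offset[i]] + steps$amplitude[i]
  }
  g_KL_vec <- c(HTC = 0, RTC = 0, IN = 0, RE = 0); g_KL_vec[type] <- g_KL
  dens <- NULL
  if (!is.null(densities)) { dens <- list(); dens[[type]] <- densities }
  rec <- simulate_thalamus(net, g_KL = g_KL_vec,
                           g_input = c(HTC = 0, RTC = 0, IN = 0, RE = 0),
                           duration = duration, dt = dt, discard = 0,
                           seed = 1,
                           stimulus = list(wave = wave, targets = type),
                           densities = dens, input_rate = 0,
                           stride_ms = 0.1,
                           traces = data.frame(pop = type, cell = 1))
  list(t = rec$t, v = as.numeric(rec$traces[, 1]), spikes = rec$spikes$time)
}
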