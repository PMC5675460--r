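# Shared fixtures: miniature networks, synthetic recordings, and a cache of
# full-size simulation runs reused across test files.

small_sizes <- c(HTC = 16, RTC = 25, IN = 16, RE = 16)

small_network <- function(seed = 1, ...) {
  build_network(seed = seed, sizes = small_sizes, ...)
}

# A recording-shaped object around a synthetic population-voltage signal
# (mV), sampled at `fs` Hz, for exercising the analysis pipeline without a
# simulation.
synthetic_recording <- function(x, fs = 1000, discard = 0,
                                spikes = data.frame(pop = character(),
                                                    cell = integer(),
                                                    time = numeric())) {
  n <- length(x)
  t <- seq(0, by = 1000 / fs, length.out = n)
  mv <- cbind(HTC = x, RTC = x, IN = x, RE = x)
  structure(list(spikes = spikes, t = t, mean_v = mv,
                 sizes = c(HTC = 49, RTC = 144, IN = 64, RE = 100),
                 dt = 0.02, stride_ms = 1000 / fs,
                 duration = max(t), discard = discard, seed = 0,
                 params = list(trigger = list(onset = 1000))),
            class = "thalamic_recording")
}

# Memoised full-size runs shared between acceptance criteria.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Scaled-down study runs used by the criterion tests: full-size network,
# 2.5 s of simulated time (0.5 s settling + 2 s analysed), two seeds.
state_run <- function(state, seed, duration = 2500, network = NULL, ...) {
  key <- paste0(state, "_", seed, "_", duration,
                if (length(list(...))) paste0("_", digest_args(list(...))) else "")
  cached(key, run_named_state(state, seed = seed, duration = duration,
                              network = network, ...))
}

digest_args <- function(x) {
  paste(vapply(deparse(x), paste0, ""), collapse = "")
}

state_frequency <- function(rec) {
  dominant_frequency(compute_slfp(rec))
}
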