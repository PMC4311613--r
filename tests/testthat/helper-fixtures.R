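# Shared fixture builders; everything is generated in code at test time.

# Binned train from explicit bin values (bypasses event times).
binned_from_values <- function(values, bin_width = 0.002,
                               channel = NA_integer_) {
  structure(list(values = as.numeric(values), bin_width = bin_width,
                 duration = length(values) * bin_width, mode = "binary",
                 channel = as.integer(channel), stimulus = NA_integer_,
                 repetition = NA_integer_),
            class = "binned_train")
}

# Correlogram from explicit values (for metric unit tests).
correlogram_from_values <- function(values, bin_width = 0.002,
                                    kind = "normalized") {
  L <- (length(values) - 1L) %/% 2L
  structure(list(lags = seq.int(-L, L), values = as.numeric(values),
                 bin_width = bin_width, kind = kind,
                 pair = c(NA_integer_, NA_integer_)),
            class = "correlogram")
}

# Exhaustive double-loop cross-correlogram: the brute-force oracle for
# the lagged coincidence sum, independent of the compiled path.
brute_correlogram <- function(x, y, L) {
  n <- length(x)
  vapply(seq.int(-L, L), function(tau) {
    acc <- 0
    for (t in seq_len(n)) {
      s <- t + tau
      if (s >= 1 && s <= n) acc <- acc + x[t] * y[s]
    }
    acc
  }, numeric(1))
}

# Homogeneous Poisson spike train on [0, duration).
poisson_train <- function(rate, duration, ...) {
  n <- rpois(1, rate * duration)
  spike_train(sort(runif(n, 0, duration)) * (1 - 1e-12), duration, ...)
}

# Small complete metric table covering an I x J x K grid.
toy_metric_table <- function(I = 3, J = 2, K = 4, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(pair = paste0("p", seq_len(I)),
                     stimulus = seq_len(J), repetition = seq_len(K),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$kappa_sync <- runif(nrow(tab))
  tab
}

# Tiny fast experiment used where the full default scale is not needed:
# 2x2 grid, 2 stimuli, short trials.
tiny_experiment <- function(seed = 1, injection_rate = 5,
                            deactivation_multiplier = 0.3, ...) {
  simulate_experiment(
    grid = electrode_grid(2, 2, 500),
    orientations = c(0, 90), directions = "fwd",
    cycles_per_phase = 1, reps_per_cycle = 4,
    durations = c(gray = 0.5, static = 0.5, moving = 1),
    background_rate = 15, injection_rate = injection_rate,
    assemblies = list(list(channels = c(1, 2), preferred = 1L)),
    phase_multipliers = c(warm = 1,
                          deactivation = deactivation_multiplier,
                          rewarm = 1),
    seed = seed, ...)
}
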