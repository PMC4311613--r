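test_that("simulate_tensor honors noise level, rank and determinism", {
  sim0 <- simulate_tensor(c(6, 5, 7), 2, noise_sd = 0, seed = 55)
  fit <- als_fit(sim0$tensor, 2, n_starts = 3, seed = 56)
  expect_lt(sim0$noise_sd_abs, 1e-12)
  expect_lt(100 - fit$explained_variance, 1e-6)
  # bitwise determinism under a fixed seed
  again <- simulate_tensor(c(6, 5, 7), 2, noise_sd = 0, seed = 55)
  expect_identical(sim0$tensor, again$tensor)
  expect_identical(sim0$truth$A, again$truth$A)
  # empirical noise SD matches the configured one at large size
  big <- simulate_tensor(c(25, 20, 20), 2, noise_sd = 0.5, seed = 57)
  signal <- reconstruct(big$truth)
  emp <- sd(as.vector(big$tensor - signal))
  expect_equal(emp, big$noise_sd_abs, tolerance = 0.05)
  # truth is returned in the fitted-model normalization
  expect_equal(colSums(big$truth$B^2), rep(1, 2), tolerance = 1e-10)
  expect_equal(colSums(big$truth$C^2), rep(1, 2), tolerance = 1e-10)
})

test_that("the default experiment reproduces the recording-session structure", {
  ds <- simulate_experiment(background_rate = 2, injection_rate = 0.2,
                            seed = 59)
  expect_equal(nrow(ds$stimuli), 8L)
  expect_equal(length(ds$phases), 63L)
  expect_equal(unique(ds$phases[1:21]), "warm")
  expect_equal(unique(ds$phases[22:42]), "deactivation")
  expect_equal(unique(ds$phases[43:63]), "rewarm")
  expect_equal(ds$duration, 8)
  expect_equal(length(live_channels(ds$grid)), 15L)
  expect_equal(nrow(enumerate_pairs(ds$grid)), 105L)
  gt <- attr(ds, "ground_truth")
  expect_equal(gt$truth$n_components, 3L)
  expect_equal(gt$truth$dims, c(105L, 8L, 63L))
})

test_that("experiment generation is a pure function of config and seed", {
  d1 <- tiny_experiment(seed = 61)
  d2 <- tiny_experiment(seed = 61)
  expect_identical(d1$spikes, d2$spikes)
  d3 <- tiny_experiment(seed = 62)
  expect_false(identical(d1$spikes, d3$spikes))
})

test_that("zero injection gives a null synchrony table centered on zero", {
  set.seed(63)
  vals <- numeric(0)
  for (s in 1:12) {
    ds <- simulate_experiment(
      grid = electrode_grid(2, 2, 500),
      orientations = 0, directions = "fwd",
      cycles_per_phase = 1, reps_per_cycle = 2,
      durations = c(gray = 1, static = 1, moving = 2),
      background_rate = 20, injection_rate = 0,
      assemblies = list(), seed = 700 + s)
    # use the signed peak (no clamping) to test unbiasedness around 0
    tab <- synchrony_table(ds, max_lag = 10)
    pairs <- enumerate_pairs(ds$grid)
    for (p in seq_len(nrow(pairs))) {
      x <- bin_spike_train(get_train(ds, pairs$ch1[p], 1, 1), 0.002)
      y <- bin_spike_train(get_train(ds, pairs$ch2[p], 1, 1), 0.002)
      nc <- normalized_correlogram(x, y, 10)
      vals <- c(vals, nc$values[11])
    }
  }
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se + 1e-12)
})

test_that("a deactivation multiplier below 1 depresses synchrony in the middle phase", {
  diffs <- vapply(1:8, function(s) {
    ds <- tiny_experiment(seed = 800 + s, injection_rate = 8,
                          deactivation_multiplier = 0.2)
    tab <- synchrony_table(ds, max_lag = 10)
    inj <- tab[tab$pair == "1-2", ]
    warm <- mean(inj$kappa_sync[inj$repetition <= 4])
    deact <- mean(inj$kappa_sync[inj$repetition > 4 &
                                   inj$repetition <= 8])
    warm - deact
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_lt(wilcox.test(diffs, alternative = "greater",
                        exact = FALSE)$p.value, 0.01)
})

test_that("oscillatory co-modulation raises gamma-band synchrony for modulated pairs", {
  res <- vapply(1:6, function(s) {
    ds <- simulate_experiment(
      grid = electrode_grid(2, 2, 500),
      orientations = 0, directions = "fwd",
      cycles_per_phase = 1, reps_per_cycle = 2,
      durations = c(gray = 0, static = 0, moving = 6),
      background_rate = 60, injection_rate = 0, assemblies = list(),
      osc_depth = 0.9, osc_freq = 40, osc_channels = c(1, 2),
      seed = 900 + s)
    tab <- synchrony_table(ds, metrics = "oscsync", max_lag = 50)
    mod <- mean(tab$kappa_oscsync[tab$pair == "1-2"])
    unmod <- mean(tab$kappa_oscsync[tab$pair == "3-4"])
    mod - unmod
  }, numeric(1))
  expect_gt(mean(res), 0)
  expect_lt(wilcox.test(res, alternative = "greater",
                        exact = FALSE)$p.value, 0.05)
})

test_that("config invariants are enforced and implausible rates warn", {
  expect_error(simulate_experiment(background_rate = -1), "background_rate")
  expect_error(simulate_experiment(osc_depth = 1.5), "osc_depth")
  expect_error(
    simulate_experiment(
      grid = electrode_grid(2, 2, 500, dead_channels = 4),
      assemblies = list(list(channels = c(1, 4), preferred = 1L))),
    "dead")
  expect_warning(
    tiny_experiment(seed = 65, injection_rate = 100),
    "exceeds the background")
})
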