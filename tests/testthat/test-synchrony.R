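test_that("kappa_sync clamps negative maxima and picks the window maximum", {
  neg <- correlogram_from_values(c(-1, -2, -1, -2, -1, -2, -1))
  expect_equal(as.numeric(kappa_sync(neg)), 0)
  expect_true(is.na(attr(kappa_sync(neg), "lag_bins")))
  v <- numeric(21); v[11 - 2] <- 0.7  # lag -2 bins = -4 ms
  pk <- kappa_sync(correlogram_from_values(v))
  expect_equal(as.numeric(pk), 0.7)
  expect_equal(attr(pk, "lag_bins"), -2L)
})

test_that("kappa_sync equals an exhaustive scan of in-window lags", {
  set.seed(5)
  for (i in 1:50) {
    vals <- rnorm(41)
    cg <- correlogram_from_values(vals)
    w <- 2L  # floor(0.005 / 0.002)
    oracle <- max(0, max(vals[abs(seq(-20, 20)) <= w]))
    expect_equal(as.numeric(kappa_sync(cg)), oracle)
  }
})

test_that("kappa_sync tie-breaking reports smallest |lag|, negative first", {
  v <- numeric(11)
  v[6 - 2] <- v[6 + 1] <- 0.5  # ties at lags -2 and +1
  expect_equal(attr(kappa_sync(correlogram_from_values(v)), "lag_bins"), 1L)
  v2 <- numeric(11)
  v2[6 - 1] <- v2[6 + 1] <- 0.5  # ties at -1 and +1
  expect_equal(attr(kappa_sync(correlogram_from_values(v2)), "lag_bins"),
               -1L)
})

test_that("kappa_sync respects the raw-kind guard and window bound", {
  raw <- correlogram_from_values(1:5, kind = "raw")
  expect_error(kappa_sync(raw), "normalized")
  small <- correlogram_from_values(c(0, 1, 0))  # max lag 1 bin = 2 ms
  expect_error(kappa_sync(small, t_sync = 0.005), "lag range")
})

test_that("kappa_oscsync is 1 on the full band and 0 off-DC for constants", {
  set.seed(9)
  cg <- correlogram_from_values(rnorm(101))
  nyq <- 1 / (2 * 0.002)
  expect_equal(kappa_oscsync(cg, 0, nyq), 1.0)
  const <- correlogram_from_values(rep(0.4, 101))
  expect_equal(kappa_oscsync(const, 30, 50), 0, tolerance = 1e-12)
})

test_that("a pure tone's power concentrates in its band", {
  # 40 Hz cosine sampled at 2 ms over exactly 2 cycles (N = 25, odd)
  n <- 25
  t <- (0:(n - 1)) * 0.002
  tone <- cos(2 * pi * 40 * t)
  k <- kappa_oscsync(correlogram_from_values(tone), 30, 50)
  expect_equal(k, 1.0, tolerance = 1e-9)
})

test_that("kappa_oscsync stays within [0, 1] on random correlograms", {
  set.seed(31)
  for (i in 1:50) {
    cg <- correlogram_from_values(rnorm(2 * sample(10:60, 1) + 1))
    k <- kappa_oscsync(cg, 30, 50)
    expect_gte(k, 0)
    expect_lte(k, 1 + 1e-12)
  }
})

test_that("total DFT power matches Parseval's identity", {
  set.seed(33)
  vals <- rnorm(101)
  pw <- Mod(fft(vals))^2
  expect_equal(sum(pw) / 101, sum(vals^2), tolerance = 1e-9)
  # denominator used by the ratio therefore equals N * sum(lambda^2)
  full <- kappa_oscsync(correlogram_from_values(vals), 0, 250)
  expect_equal(full, 1.0)
})

test_that("kappa_oscsync guards degenerate inputs and bad bands", {
  zero <- correlogram_from_values(numeric(11))
  expect_error(kappa_oscsync(zero), "identically zero")
  cg <- correlogram_from_values(rnorm(11))
  expect_error(kappa_oscsync(cg, 100, 400), "Nyquist")
  expect_error(kappa_oscsync(cg, 50, 30), "f_min")
})

test_that("kappa_sync grows with the number of injected coincidences", {
  # monotone in expectation: more shared events -> larger peak
  set.seed(41)
  mean_kappa <- function(n_coinc) {
    reps <- 20
    out <- numeric(reps)
    for (r in seq_len(reps)) {
      dur <- 4
      shared <- runif(n_coinc, 0.1, dur - 0.1)
      x <- bin_spike_train(
        spike_train(sort(c(runif(40, 0, dur), shared)), dur), 0.002)
      y <- bin_spike_train(
        spike_train(sort(c(runif(40, 0, dur), shared)), dur), 0.002)
      out[r] <- kappa_sync(normalized_correlogram(x, y, 10))
    }
    mean(out)
  }
  ks <- vapply(c(0, 10, 30), mean_kappa, numeric(1))
  expect_true(ks[1] < ks[2] && ks[2] < ks[3])
})

test_that("synchrony_table covers every pair x stimulus x repetition cell", {
  ds <- tiny_experiment(seed = 6)
  tab <- synchrony_table(ds, metrics = c("sync", "oscsync"), max_lag = 25)
  expect_equal(nrow(tab), 6 * 2 * 12)  # C(4,2) pairs, 2 stimuli, 12 reps
  expect_false(anyNA(tab$kappa_sync))
  expect_false(anyNA(tab$kappa_oscsync))
  expect_true(all(tab$kappa_sync >= 0))
  expect_true(all(tab$kappa_oscsync >= 0 & tab$kappa_oscsync <= 1))
  # same result from the per-correlogram module path, spot-checked
  row <- tab[17, ]
  x <- bin_spike_train(get_train(ds, row$ch1, row$stimulus,
                                 row$repetition), 0.002)
  y <- bin_spike_train(get_train(ds, row$ch2, row$stimulus,
                                 row$repetition), 0.002)
  expect_equal(row$kappa_sync,
               as.numeric(kappa_sync(normalized_correlogram(x, y, 25))))
})

test_that("analysis-window restriction changes only the analyzed epoch", {
  ds <- tiny_experiment(seed = 8)
  full <- synchrony_table(ds, max_lag = 10)
  late <- synchrony_table(ds, max_lag = 10, window = c(1, 2))
  expect_equal(nrow(full), nrow(late))
  expect_false(isTRUE(all.equal(full$kappa_sync, late$kappa_sync)))
})
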