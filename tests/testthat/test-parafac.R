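test_that("reconstruct matches the triple-loop trilinear sum", {
  m <- structure(list(n_components = 1L, A = matrix(2), B = matrix(3),
                      C = matrix(4), dims = c(1L, 1L, 1L), labels = NULL),
                 class = "parafac_model")
  expect_equal(as.vector(reconstruct(m)), 24)
  set.seed(4)
  dims <- c(4L, 3L, 5L)
  m2 <- structure(list(n_components = 2L,
                       A = matrix(rnorm(8), 4), B = matrix(rnorm(6), 3),
                       C = matrix(rnorm(10), 5), dims = dims,
                       labels = NULL),
                  class = "parafac_model")
  oracle <- array(0, dims)
  for (i in 1:4) for (j in 1:3) for (k in 1:5) for (f in 1:2)
    oracle[i, j, k] <- oracle[i, j, k] +
      m2$A[i, f] * m2$B[j, f] * m2$C[k, f]
  expect_equal(reconstruct(m2), oracle, tolerance = 1e-12)
  m2$A[] <- 0
  expect_equal(reconstruct(m2), array(0, dims))
})

test_that("ALS recovers planted rank-1 and rank-3 structure from noiseless tensors", {
  sim1 <- simulate_tensor(c(6, 5, 7), 1, noise_sd = 0, seed = 21)
  fit1 <- als_fit(sim1$tensor, 1, n_starts = 3, seed = 22)
  expect_gte(factor_match(sim1$truth, fit1)$score, 0.9999)
  sim3 <- simulate_tensor(c(6, 5, 7), 3, noise_sd = 0, seed = 23)
  fit3 <- als_fit(sim3$tensor, 3, n_starts = 5, seed = 24)
  expect_gte(fit3$explained_variance, 99.99)
  expect_gte(factor_match(sim3$truth, fit3)$score, 0.99)
})

test_that("the ALS residual is monotone non-increasing", {
  set.seed(25)
  for (i in 1:5) {
    x <- array(rnorm(120), c(5, 4, 6))
    fit <- als_fit(x, 2, n_starts = 2, seed = 30 + i, max_iter = 200)
    expect_true(all(diff(fit$fit_trace) <= 1e-10))
  }
})

test_that("uniqueness: noiseless recovery holds across many seeds", {
  scores <- vapply(1:20, function(s) {
    sim <- simulate_tensor(c(8, 6, 9), 3, noise_sd = 0, seed = 400 + s)
    fit <- als_fit(sim$tensor, 3, n_starts = 5, seed = 500 + s)
    factor_match(sim$truth, fit)$score
  }, numeric(1))
  expect_true(all(scores >= 0.99))
})

test_that("normalization fixes scale and sign without changing the reconstruction", {
  sim <- simulate_tensor(c(5, 4, 6), 2, noise_sd = 0.05, seed = 41)
  fit <- als_fit(sim$tensor, 2, n_starts = 3, seed = 42)
  expect_equal(colSums(fit$B^2), rep(1, 2), tolerance = 1e-10)
  expect_equal(colSums(fit$C^2), rep(1, 2), tolerance = 1e-10)
  for (f in 1:2) {
    expect_gt(fit$B[which.max(abs(fit$B[, f])), f], 0)
    expect_gt(fit$C[which.max(abs(fit$C[, f])), f], 0)
  }
  # components ordered by contribution
  expect_true(all(diff(colSums(fit$A^2)) <= 1e-9))
  # reconstruction is invariant under a manual rescale + inverse
  rescaled <- fit
  rescaled$A[, 1] <- fit$A[, 1] * 2
  rescaled$B[, 1] <- fit$B[, 1] / 2
  expect_equal(reconstruct(rescaled), reconstruct(fit), tolerance = 1e-9)
})

test_that("explained_variance matches the direct elementwise formula", {
  sim <- simulate_tensor(c(5, 4, 6), 2, noise_sd = 0.3, seed = 51)
  fit <- als_fit(sim$tensor, 2, n_starts = 3, seed = 52)
  direct <- 100 * (1 - sum((sim$tensor - reconstruct(fit))^2) /
                     sum(sim$tensor^2))
  expect_equal(explained_variance(fit, sim$tensor), direct,
               tolerance = 1e-10)
  expect_equal(explained_variance(fit, reconstruct(fit)), 100,
               tolerance = 1e-6)
  zero_model <- fit
  zero_model$A[] <- 0
  expect_equal(explained_variance(zero_model, sim$tensor), 0,
               tolerance = 1e-10)
  expect_error(explained_variance(fit, array(0, fit$dims)), "zero-norm")
})

test_that("component congruence matches a direct cosine loop", {
  sim <- simulate_tensor(c(6, 5, 7), 3, noise_sd = 0.1, seed = 61)
  fit <- als_fit(sim$tensor, 3, n_starts = 3, seed = 62)
  cg <- component_congruence(fit)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  for (f in 1:3) for (g in 1:3) {
    expect_equal(cg$A[f, g], cosine(fit$A[, f], fit$A[, g]),
                 tolerance = 1e-12)
    expect_equal(cg$combined[f, g],
                 cosine(fit$A[, f], fit$A[, g]) *
                   cosine(fit$B[, f], fit$B[, g]) *
                   cosine(fit$C[, f], fit$C[, g]),
                 tolerance = 1e-12)
  }
  expect_equal(diag(cg$combined), rep(1, 3), tolerance = 1e-12)
  # orthogonal columns give zero off-diagonals; duplicates give 1
  orth <- structure(list(n_components = 2L, A = diag(2)[, 1:2],
                         B = diag(2), C = diag(2), dims = c(2L, 2L, 2L),
                         labels = NULL),
                    class = "parafac_model")
  expect_equal(component_congruence(orth)$combined[1, 2], 0)
  dup <- orth
  dup$A[, 2] <- dup$A[, 1]; dup$B[, 2] <- dup$B[, 1]
  dup$C[, 2] <- dup$C[, 1]
  expect_equal(component_congruence(dup)$combined[1, 2], 1)
})

test_that("ALS rejects infeasible component counts and bad input", {
  x <- array(rnorm(24), c(2, 3, 4))
  expect_error(als_fit(x, 0), ">= 1")
  expect_error(als_fit(x, 7), "feasible")
  x[1] <- NA
  expect_error(als_fit(x, 1), "non-finite")
})

test_that("multi-start reporting includes all starts, best and median", {
  sim <- simulate_tensor(c(5, 4, 6), 2, noise_sd = 0.2, seed = 71)
  fit <- als_fit(sim$tensor, 2, n_starts = 4, seed = 72)
  expect_length(fit$start_fits$all, 4L)
  expect_equal(fit$start_fits$best, max(fit$start_fits$all))
  expect_equal(fit$explained_variance, fit$start_fits$best,
               tolerance = 1e-9)
})

test_that("model export writes labeled loading tables with metadata", {
  tab <- toy_metric_table(4, 3, 5, seed = 9)
  x <- center_tensor(build_tensor(tab))
  fit <- als_fit(x, 2, n_starts = 2, seed = 81)
  path <- withr::local_tempdir()
  write_parafac(fit, path)
  a_tab <- read.delim(file.path(path, "A.tsv"))
  expect_equal(a_tab$label, dimnames(x)[[1]])
  expect_equal(ncol(a_tab), 3L)
  meta <- jsonlite::read_json(file.path(path, "model.json"))
  expect_equal(meta$n_components, 2L)
})
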