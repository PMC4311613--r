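test_that("pair enumeration matches the grid combinatorics", {
  expect_equal(nrow(enumerate_pairs(electrode_grid(4, 4, 500,
                                                   dead_channels = 13))),
               105L)
  expect_equal(nrow(enumerate_pairs(electrode_grid(4, 4, 500))), 120L)
  g2 <- electrode_grid(1, 3, 500, dead_channels = 2)
  p <- enumerate_pairs(g2)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pair, "1-3")
  expect_error(enumerate_pairs(electrode_grid(1, 2, 500,
                                              dead_channels = 2)),
               "at least 2")
})

test_that("neighbor classification reproduces the 42/78 split and the distance rule", {
  g <- electrode_grid(4, 4, 500)
  cls <- classify_pairs(g)
  expect_equal(nrow(cls$neighboring), 42L)
  expect_equal(nrow(cls$remote), 78L)
  # partition property
  expect_equal(sort(c(cls$neighboring$pair, cls$remote$pair)),
               sort(enumerate_pairs(g)$pair))
  expect_length(intersect(cls$neighboring$pair, cls$remote$pair), 0L)
  # brute-force distance oracle over all pairs
  pos <- g$positions
  for (i in seq_len(nrow(cls$neighboring))) {
    p <- cls$neighboring[i, ]
    d <- sqrt(sum((pos[pos$channel == p$ch1, c("x", "y")] -
                     pos[pos$channel == p$ch2, c("x", "y")])^2))
    expect_lte(d, sqrt(2) * g$spacing + 1e-9)
  }
  # 1x2 grid: single neighboring pair, nothing remote
  tiny <- classify_pairs(electrode_grid(1, 2, 500))
  expect_equal(nrow(tiny$neighboring), 1L)
  expect_equal(nrow(tiny$remote), 0L)
})

test_that("build_tensor places values by (pair, stimulus, repetition) key", {
  tab <- toy_metric_table(3, 2, 4)
  x <- build_tensor(tab)
  expect_equal(dim(x), c(3L, 2L, 4L))
  for (r in c(1, 9, 24)) {
    expect_equal(
      x[tab$pair[r], as.character(tab$stimulus[r]),
        as.character(tab$repetition[r])],
      tab$kappa_sync[r])
  }
})

test_that("build_tensor reports missing and duplicated cells by key", {
  tab <- toy_metric_table(3, 2, 4)
  expect_error(build_tensor(tab[-5, ]), "missing cell.*pair=")
  expect_error(build_tensor(rbind(tab, tab[2, ])), "duplicated cell")
})

test_that("flatten is the inverse of build on complete tables", {
  tab <- toy_metric_table(4, 3, 5, seed = 2)
  x <- build_tensor(tab)
  back <- flatten_tensor(x)
  x2 <- build_tensor(back)
  expect_equal(unclass(x2), unclass(x))
})

test_that("sequential centering matches a naive loop and zeroes the last mode", {
  set.seed(3)
  x <- array(rnorm(60), c(4, 3, 5))
  naive <- x
  for (m in 1:3) {
    mu <- apply(naive, setdiff(1:3, m), mean)
    for (i in 1:4) for (j in 1:3) for (k in 1:5) {
      idx <- c(i, j, k)[setdiff(1:3, m)]
      naive[i, j, k] <- naive[i, j, k] - mu[idx[1], idx[2]]
    }
  }
  xt <- structure(x, metric = "m", centered = character(),
                  class = c("synchrony_tensor", "array"))
  got <- center_tensor(xt, 1:3)
  expect_equal(unclass(got), unclass(naive), ignore_attr = TRUE,
               tolerance = 1e-12)
  # last-centered mode has exactly zero fiber means
  expect_equal(max(abs(apply(got, c(1, 2), mean))), 0, tolerance = 1e-12)
  # fully centered tensor sums to zero
  expect_equal(sum(got), 0, tolerance = 1e-10)
  # idempotence on already-centered input
  again <- center_tensor(got, 1:3)
  expect_equal(unclass(again), unclass(got), ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("centering guards degenerate modes", {
  x <- structure(array(1, c(2, 1, 3)), metric = "m",
                 centered = character(),
                 class = c("synchrony_tensor", "array"))
  expect_error(center_tensor(x, 2), "extent 1")
})

test_that("subset_tensor slices pairs and keeps labels", {
  tab <- toy_metric_table(5, 2, 3)
  x <- build_tensor(tab)
  all_sub <- subset_tensor(x, dimnames(x)[[1]])
  expect_equal(unclass(all_sub), unclass(x))
  two <- subset_tensor(x, c("p2", "p4"))
  expect_equal(dim(two)[1], 2L)
  expect_equal(dimnames(two)[[1]], c("p2", "p4"))
  expect_error(subset_tensor(x, "p9"), "unknown pair")
})

test_that("neighboring and remote subsets of the full-grid tensor have the printed sizes", {
  g <- electrode_grid(4, 4, 500)
  pairs <- enumerate_pairs(g)
  tab <- expand.grid(pair = pairs$pair, stimulus = 1:2, repetition = 1:3,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$kappa_sync <- seq_len(nrow(tab))
  x <- build_tensor(tab, pair_levels = pairs$pair)
  cls <- classify_pairs(g)
  expect_equal(dim(subset_tensor(x, cls$neighboring))[1], 42L)
  expect_equal(dim(subset_tensor(x, cls$remote))[1], 78L)
})
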