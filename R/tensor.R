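#' Enumerate live electrode pairs
#'
#' All unordered pairs of live channels in canonical order (low id first),
#' sorted lexicographically. A 4 x 4 grid with one dead channel yields the
#' 105 pairs analysed throughout; with no dead channel, choose(16, 2) = 120.
#'
#' @param grid an [electrode_grid()].
#' @return data.frame with columns `pair` (label `"ch1-ch2"`), `ch1`, `ch2`.
#' @export
enumerate_pairs <- function(grid) {
  live <- sort(live_channels(grid))
  if (length(live) < 2L) stop("need at least 2 live channels")
  cmb <- combn(live, 2L)
  data.frame(pair = paste(cmb[1, ], cmb[2, ], sep = "-"),
             ch1 = cmb[1, ], ch2 = cmb[2, ])
}

#' Classify electrode pairs as neighboring or remote
#'
#' Two electrodes are neighboring when their Euclidean distance is at most
#' `sqrt(2)` times the grid spacing, i.e. `(dx)^2 + (dy)^2 <= 2 * d_grid^2`
#' — lattice neighbors including diagonals. On a full 4 x 4 grid this gives
#' 42 neighboring and 78 remote pairs.
#'
#' @param grid an [electrode_grid()].
#' @return list with data.frames `neighboring` and `remote` (same columns
#'   as [enumerate_pairs()]), a disjoint partition of all live pairs.
#' @export
classify_pairs <- function(grid) {
  pairs <- enumerate_pairs(grid)
  pos <- grid$positions
  xy <- function(ch, col) pos[[col]][match(ch, pos$channel)]
  d2 <- (xy(pairs$ch1, "x") - xy(pairs$ch2, "x"))^2 +
    (xy(pairs$ch1, "y") - xy(pairs$ch2, "y"))^2
  near <- d2 <= 2 * grid$spacing^2 + 1e-9
  list(neighboring = pairs[near, , drop = FALSE],
       remote = pairs[!near, , drop = FALSE])
}

#' Assemble a metric table into a synchrony tensor
#'
#' Places one scalar statistic per (pair, stimulus, repetition) cell into a
#' three-way array. The table must cover the full I x J x K grid exactly
#' once; duplicated or missing cells are an error naming the offending key.
#'
#' @param table long-format data.frame with columns `pair`, `stimulus`,
#'   `repetition` and the metric column.
#' @param metric name of the metric column, default `"kappa_sync"`.
#' @param pair_levels,stimulus_levels,repetition_levels optional explicit
#'   axis orders; by default numeric axes are sorted ascending and
#'   character axes (pair labels) keep their order of first appearance in
#'   the table, which for [synchrony_table()] output is the canonical
#'   [enumerate_pairs()] order.
#' @return object of class `synchrony_tensor`: a 3-way numeric array with
#'   `dimnames` (pair, stimulus, repetition) plus attributes `metric` and
#'   `centered` (character vector of centering steps applied, empty here).
#' @export
build_tensor <- function(table, metric = "kappa_sync", pair_levels = NULL,
                         stimulus_levels = NULL, repetition_levels = NULL) {
  need <- c("pair", "stimulus", "repetition", metric)
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  lev <- function(given, col) {
    if (!is.null(given)) as.character(given)
    else {
      v <- unique(table[[col]])
      if (is.numeric(v)) as.character(sort(v)) else as.character(v)
    }
  }
  pl <- lev(pair_levels, "pair")
  sl <- lev(stimulus_levels, "stimulus")
  rl <- lev(repetition_levels, "repetition")
  ip <- match(as.character(table$pair), pl)
  is_ <- match(as.character(table$stimulus), sl)
  ir <- match(as.character(table$repetition), rl)
  if (anyNA(ip) || anyNA(is_) || anyNA(ir))
    stop("table contains keys outside the requested axis levels")
  idx <- cbind(ip, is_, ir)
  flat <- (ir - 1L) * length(pl) * length(sl) + (is_ - 1L) * length(pl) + ip
  if (anyDuplicated(flat)) {
    d <- which(duplicated(flat))[1L]
    stop(sprintf("duplicated cell (pair=%s, stimulus=%s, repetition=%s)",
                 table$pair[d], table$stimulus[d], table$repetition[d]))
  }
  x <- array(NA_real_, dim = c(length(pl), length(sl), length(rl)),
             dimnames = list(pair = pl, stimulus = sl, repetition = rl))
  x[idx] <- table[[metric]]
  if (anyNA(x)) {
    m <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell (pair=%s, stimulus=%s, repetition=%s)",
                 pl[m[1]], sl[m[2]], rl[m[3]]))
  }
  new_synchrony_tensor(x, metric = metric, centered = character())
}

new_synchrony_tensor <- function(x, metric, centered) {
  structure(x, metric = metric, centered = centered,
            class = c("synchrony_tensor", "array"))
}

#' @export
print.synchrony_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("synchrony_tensor [%d pairs x %d stimuli x %d repetitions]",
              d[1], d[2], d[3]),
      sprintf("metric %s", attr(x, "metric")),
      if (length(attr(x, "centered")))
        sprintf("centered: %s", paste(attr(x, "centered"), collapse = ", "))
      else "uncentered",
      sep = "; ")
  cat("\n")
  invisible(x)
}

#' Sequential single-mode centering of a tensor
#'
#' For each requested mode in order, subtracts from every entry the mean
#' over that mode's index (holding the other two indices fixed), each step
#' operating on the result of the previous one. Centering a later mode can
#' perturb the zero means achieved for an earlier one; only the
#' last-centered mode's fiber means are exactly zero in general, and a
#' fully centered tensor always sums to zero. No scaling is applied
#' anywhere in the pipeline.
#'
#' @param x a `synchrony_tensor` (or plain 3-way array).
#' @param modes ordered subset of `1:3`, default `1:3` (pair, then
#'   stimulus, then repetition).
#' @return centered `synchrony_tensor`; attribute `centered` records the
#'   steps applied, e.g. `"mode1"`, `"mode2"`, `"mode3"`.
#' @export
center_tensor <- function(x, modes = 1:3) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  modes <- as.integer(modes)
  if (anyDuplicated(modes) || !all(modes %in% 1:3))
    stop("'modes' must be a duplicate-free subset of 1:3")
  if (any(dim(x)[modes] < 2L))
    stop("cannot center a mode of extent 1")
  out <- x
  for (m in modes) {
    mu <- apply(out, setdiff(1:3, m), mean)
    out <- sweep(out, setdiff(1:3, m), mu, "-")
  }
  new_synchrony_tensor(
    out,
    metric = attr(x, "metric", exact = TRUE),
    centered = c(attr(x, "centered", exact = TRUE),
                 paste0("mode", modes)))
}

#' Subset a synchrony tensor by electrode pair
#'
#' Slices the pair mode down to a chosen set of pairs (e.g. the
#' neighboring or remote set from [classify_pairs()]), keeping labels.
#'
#' @param x a `synchrony_tensor`.
#' @param pairs character vector of pair labels, or a data.frame with a
#'   `pair` column.
#' @return `synchrony_tensor` with first dimension `length(pairs)`.
#' @export
subset_tensor <- function(x, pairs) {
  stopifnot(inherits(x, "synchrony_tensor"))
  if (is.data.frame(pairs)) pairs <- pairs$pair
  pairs <- as.character(pairs)
  unknown <- setdiff(pairs, dimnames(x)[[1]])
  if (length(unknown))
    stop("unknown pair(s): ", paste(unknown, collapse = ", "))
  new_synchrony_tensor(
    x[pairs, , , drop = FALSE],
    metric = attr(x, "metric", exact = TRUE),
    centered = attr(x, "centered", exact = TRUE))
}

#' Flatten a synchrony tensor back to a long table
#'
#' Inverse of [build_tensor()] on complete tables: one row per cell with
#' the axis labels and the metric value.
#'
#' @param x a `synchrony_tensor`.
#' @return data.frame with columns `pair`, `stimulus`, `repetition`, and
#'   the metric value under its metric name.
#' @export
flatten_tensor <- function(x) {
  stopifnot(inherits(x, "synchrony_tensor"))
  dn <- dimnames(x)
  out <- expand.grid(pair = dn[[1]], stimulus = dn[[2]],
                     repetition = dn[[3]],
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out[[attr(x, "metric", exact = TRUE)]] <- as.vector(unclass(x))
  out
}
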