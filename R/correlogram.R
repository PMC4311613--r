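#' Cross-correlograms of binned spike trains
#'
#' `raw_correlogram()` computes the lagged coincidence count
#' \eqn{\lambda^{raw}(\tau) = \sum_t x(t)\, y(t+\tau)} for integer lags
#' \eqn{\tau \in [-L, L]} (bins); products falling outside the trains
#' contribute zero. `jitter_correlogram()` convolves *both* trains with the
#' homogeneous jitter kernel before correlating, which is equivalent in
#' expectation to uniformly jittering spike times within a window of
#' `t_jitter` seconds and so estimates the rate-driven (chance) coincidence
#' count. `normalized_correlogram()` is their elementwise difference: what
#' remains after chance coincidences are subtracted.
#'
#' @param x,y [bin_spike_train()] outputs of equal length and bin width.
#' @param max_lag maximum lag `L` in bins (default 50, i.e. +/-100 ms at
#'   2 ms bins).
#' @param t_jitter jitter window in seconds, default 0.006.
#' @return an object of class `correlogram`: list with `lags` (integer,
#'   `-L..L`), `values`, `bin_width`, `kind` (`"raw"`, `"jitter"` or
#'   `"normalized"`), `pair` (channel ids), and `t_jitter` where relevant.
#' @examples
#' a <- bin_spike_train(spike_train(0.002, 0.008), 0.002)
#' raw_correlogram(a, a, max_lag = 1)$values  # 0 1 0
#' @export
raw_correlogram <- function(x, y, max_lag = 50L) {
  check_binned_pair(x, y, max_lag)
  vals <- .cc_lagged(x$values, y$values, as.integer(max_lag))
  new_correlogram(vals, max_lag, x$bin_width, "raw",
                  pair = c(x$channel, y$channel))
}

#' Homogeneous jitter kernel
#'
#' Equal-entry kernel of length `round(t_jitter / bin_width)` summing to 1;
#' convolving a binned train with it spreads each spike uniformly over the
#' jitter window. `t_jitter = bin_width` gives the identity kernel.
#'
#' @param t_jitter jitter window (s); must be at least `bin_width`.
#' @param bin_width bin width (s).
#' @return numeric vector of equal entries summing to 1.
#' @examples
#' jitter_kernel(0.006, 0.002)  # 1/3 1/3 1/3
#' @export
jitter_kernel <- function(t_jitter, bin_width) {
  if (!is.numeric(t_jitter) || !is.numeric(bin_width) || bin_width <= 0)
    stop("'t_jitter' and 'bin_width' must be positive numbers")
  if (t_jitter < bin_width - 1e-12)
    stop("'t_jitter' must be at least one bin width")
  n <- max(1L, as.integer(round(t_jitter / bin_width)))
  rep(1 / n, n)
}

#' @rdname raw_correlogram
#' @export
jitter_correlogram <- function(x, y, max_lag = 50L, t_jitter = 0.006) {
  check_binned_pair(x, y, max_lag)
  k <- jitter_kernel(t_jitter, x$bin_width)
  xs <- .conv_same(x$values, k)
  ys <- .conv_same(y$values, k)
  vals <- .cc_lagged(xs, ys, as.integer(max_lag))
  cg <- new_correlogram(vals, max_lag, x$bin_width, "jitter",
                        pair = c(x$channel, y$channel))
  cg$t_jitter <- t_jitter
  cg
}

#' @rdname raw_correlogram
#' @export
normalized_correlogram <- function(x, y, max_lag = 50L, t_jitter = 0.006) {
  raw <- raw_correlogram(x, y, max_lag)
  jit <- jitter_correlogram(x, y, max_lag, t_jitter)
  out <- raw
  out$values <- raw$values - jit$values
  out$kind <- "normalized"
  out$t_jitter <- t_jitter
  out
}

new_correlogram <- function(values, max_lag, bin_width, kind, pair) {
  structure(list(lags = seq.int(-max_lag, max_lag),
                 values = as.numeric(values),
                 bin_width = bin_width, kind = kind, pair = pair),
            class = "correlogram")
}

check_binned_pair <- function(x, y, max_lag) {
  if (!inherits(x, "binned_train") || !inherits(y, "binned_train"))
    stop("'x' and 'y' must be binned_train objects")
  if (length(x$values) != length(y$values))
    stop("binned trains have different lengths")
  if (abs(x$bin_width - y$bin_width) > 1e-12)
    stop("binned trains have different bin widths")
  if (!is.numeric(max_lag) || max_lag < 1)
    stop("'max_lag' must be >= 1")
  invisible(TRUE)
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("correlogram (%s): lags %+d..%+d bins, bin %g ms%s\n",
              x$kind, min(x$lags), max(x$lags), 1000 * x$bin_width,
              if (!is.null(x$t_jitter))
                sprintf(", t_jitter %g ms", 1000 * x$t_jitter) else ""))
  invisible(x)
}

#' Export a correlogram as a tab-separated table
#'
#' Writes a `# key: value` metadata header block (kind, bin width, jitter
#' window, channel pair) followed by `lag_bins`/`lag_s`/`value` columns.
#'
#' @param cg a `correlogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_correlogram <- function(cg, path) {
  stopifnot(inherits(cg, "correlogram"))
  hdr <- c(sprintf("# kind: %s", cg$kind),
           sprintf("# bin_width_s: %g", cg$bin_width),
           if (!is.null(cg$t_jitter))
             sprintf("# t_jitter_s: %g", cg$t_jitter),
           if (!all(is.na(cg$pair)))
             sprintf("# pair: %s", paste(cg$pair, collapse = "-")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(data.frame(lag_bins = cg$lags,
                         lag_s = cg$lags * cg$bin_width,
                         value = cg$values),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
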