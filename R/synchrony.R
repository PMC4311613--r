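#' Synchrony statistic from a normalized correlogram
#'
#' The largest positive value of the normalized correlogram within an
#' inclusive lag window `[-t_sync, +t_sync]` around zero; negative maxima
#' clamp to 0. The default 5 ms half-width spans +/-2 bins at 2 ms binning.
#'
#' @param cg a `correlogram` of kind `"normalized"`.
#' @param t_sync lag-window half-width in seconds, default 0.005.
#' @return non-negative scalar; attribute `lag_bins` carries the peak lag
#'   (smallest `|lag|` on ties, negative before positive), `NA` when the
#'   statistic clamps to 0.
#' @examples
#' a <- bin_spike_train(spike_train(0.05, 0.1), 0.002)
#' kappa_sync(normalized_correlogram(a, a, max_lag = 10))  # 2/3
#' @export
kappa_sync <- function(cg, t_sync = 0.005) {
  stopifnot(inherits(cg, "correlogram"))
  if (!identical(cg$kind, "normalized"))
    stop("kappa_sync expects a normalized correlogram")
  if (t_sync <= 0) stop("'t_sync' must be positive")
  w <- as.integer(floor(t_sync / cg$bin_width + 1e-9))
  if (w > max(cg$lags))
    stop("lag window exceeds the correlogram's lag range")
  in_win <- abs(cg$lags) <= w
  vals <- cg$values[in_win]
  lags <- cg$lags[in_win]
  k <- max(vals)
  if (k < 0) return(structure(0, lag_bins = NA_integer_))
  at <- lags[vals == k]
  at <- at[order(abs(at), at)][1L]
  structure(k, lag_bins = at)
}

#' Oscillatory-synchrony statistic from a normalized correlogram
#'
#' Fraction of the correlogram's discrete-Fourier power falling in a
#' frequency band: an N-point DFT of the normalized correlogram is taken
#' and the band power is divided by the total power over all N bins. Band
#' edges in Hz map to DFT bins via `m = round(f * N * bin_width)`;
#' conjugate (negative-frequency) bins `N - m` are included by default so a
#' real oscillation's full power is captured. The whole band `[0, Nyquist]`
#' gives exactly 1.
#'
#' @param cg a `correlogram` of kind `"normalized"`, not identically zero.
#' @param f_min,f_max band edges in Hz; defaults 30 and 50 (low gamma).
#' @param n_dft DFT length; defaults to the correlogram length `2L + 1`
#'   (no zero padding). Longer values zero-pad.
#' @param include_conjugate add the mirrored bins `N - m` to the band sum
#'   (default `TRUE`).
#' @param exclude_dc drop the `n = 0` bin from the *denominator* (default
#'   `FALSE`: DC stays in the total, as the power-ratio definition is
#'   written).
#' @return scalar in `[0, 1]`.
#' @export
kappa_oscsync <- function(cg, f_min = 30, f_max = 50, n_dft = NULL,
                          include_conjugate = TRUE, exclude_dc = FALSE) {
  stopifnot(inherits(cg, "correlogram"))
  if (!identical(cg$kind, "normalized"))
    stop("kappa_oscsync expects a normalized correlogram")
  if (all(cg$values == 0))
    stop("correlogram is identically zero: power ratio undefined")
  n <- if (is.null(n_dft)) length(cg$values) else as.integer(n_dft)
  if (n < length(cg$values))
    stop("'n_dft' must be at least the correlogram length")
  nyquist <- 1 / (2 * cg$bin_width)
  if (!(f_min >= 0 && f_min < f_max && f_max <= nyquist + 1e-9))
    stop("need 0 <= f_min < f_max <= Nyquist (", nyquist, " Hz)")
  sig <- c(cg$values, numeric(n - length(cg$values)))
  pw <- Mod(fft(sig))^2
  m_min <- as.integer(round(f_min * n * cg$bin_width))
  m_max <- as.integer(round(f_max * n * cg$bin_width))
  m_max <- min(m_max, n - 1L)
  band <- seq.int(m_min, m_max)
  if (include_conjugate) {
    conj_bins <- (n - band) %% n
    band <- union(band, conj_bins)
  }
  denom_idx <- if (exclude_dc) seq.int(2L, n) else seq_len(n)
  num_idx <- band + 1L
  if (exclude_dc) num_idx <- setdiff(num_idx, 1L)
  denom <- sum(pw[denom_idx])
  if (denom == 0) stop("zero spectral power outside DC: ratio undefined")
  sum(pw[num_idx]) / denom
}

#' Synchrony metric table for a whole dataset
#'
#' Runs the correlogram pipeline for every live electrode pair, stimulus
#' and repetition of a dataset and tabulates the chosen statistic(s). This
#' long-format table is the input to [build_tensor()].
#'
#' @param dataset a [spike_dataset()].
#' @param metrics character subset of `c("sync", "oscsync")`.
#' @param bin_width correlogram bin width (s), default 0.002.
#' @param max_lag correlogram half-span in bins, default 50.
#' @param t_jitter jitter-correction window (s), default 0.006.
#' @param t_sync peak-search half-width (s), default 0.005.
#' @param f_min,f_max oscillation band (Hz) for `"oscsync"`.
#' @param window optional `c(start, end)` restriction of the analysis
#'   window in seconds within the trial (default: full trial). Spike times
#'   are re-referenced to `start`.
#' @param pairs optional data.frame from [enumerate_pairs()] restricting
#'   the pairs computed (default: all live pairs).
#' @return data.frame with columns `pair`, `ch1`, `ch2`, `stimulus`,
#'   `repetition` and one column per requested metric (`kappa_sync`,
#'   `kappa_oscsync`).
#' @export
synchrony_table <- function(dataset, metrics = "sync", bin_width = 0.002,
                            max_lag = 50L, t_jitter = 0.006,
                            t_sync = 0.005, f_min = 30, f_max = 50,
                            window = NULL, pairs = NULL) {
  stopifnot(inherits(dataset, "spike_dataset"))
  metrics <- match.arg(metrics, c("sync", "oscsync"), several.ok = TRUE)
  if (is.null(pairs)) pairs <- enumerate_pairs(dataset$grid)
  t0 <- 0
  duration <- dataset$duration
  sp <- dataset$spikes
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2],
              window[1] >= 0, window[2] <= dataset$duration)
    sp <- sp[sp$time_s >= window[1] & sp$time_s < window[2], , drop = FALSE]
    t0 <- window[1]
    duration <- window[2] - window[1]
  }
  n_bins <- max(1L, as.integer(ceiling(duration / bin_width - 1e-9)))
  kern <- jitter_kernel(t_jitter, bin_width)
  stimuli <- sort(unique(dataset$stimuli$stimulus))
  reps <- seq_along(dataset$phases)
  n_cell <- nrow(pairs) * length(stimuli) * length(reps)
  # Pre-binned binary trains per (channel, stimulus, repetition): binning
  # once per train instead of once per pair keeps the full experiment fast.
  bin_of <- function(times) {
    idx <- pmin(floor((times - t0) / bin_width), n_bins - 1L) + 1L
    pmin(tabulate(idx, nbins = n_bins), 1L)
  }
  key <- function(ch, st, rp) paste(ch, st, rp, sep = ".")
  sp_split <- split(sp$time_s, key(sp$channel, sp$stimulus, sp$repetition))
  get_binned <- function(ch, st, rp) {
    tm <- sp_split[[key(ch, st, rp)]]
    if (is.null(tm)) numeric(n_bins) else bin_of(tm)
  }
  L <- as.integer(max_lag)
  out <- data.frame(pair = character(n_cell), ch1 = integer(n_cell),
                    ch2 = integer(n_cell), stimulus = integer(n_cell),
                    repetition = integer(n_cell))
  if ("sync" %in% metrics) out$kappa_sync <- NA_real_
  if ("oscsync" %in% metrics) out$kappa_oscsync <- NA_real_
  w_bins <- as.integer(floor(t_sync / bin_width + 1e-9))
  if (w_bins > L) stop("'t_sync' window exceeds 'max_lag'")
  row <- 0L
  for (st in stimuli) {
    # bin all channels once per (stimulus, repetition)
    for (rp in reps) {
      binned <- lapply(seq_len(nrow(dataset$grid$positions)), function(ch)
        if (ch %in% live_channels(dataset$grid)) get_binned(ch, st, rp)
        else NULL)
      smoothed <- lapply(binned, function(v)
        if (is.null(v)) NULL else .conv_same(v, kern))
      for (p in seq_len(nrow(pairs))) {
        row <- row + 1L
        c1 <- pairs$ch1[p]; c2 <- pairs$ch2[p]
        lam <- .cc_lagged(binned[[c1]], binned[[c2]], L) -
          .cc_lagged(smoothed[[c1]], smoothed[[c2]], L)
        out$pair[row] <- pairs$pair[p]
        out$ch1[row] <- c1; out$ch2[row] <- c2
        out$stimulus[row] <- st; out$repetition[row] <- rp
        if ("sync" %in% metrics) {
          k <- max(lam[seq.int(L + 1L - w_bins, L + 1L + w_bins)])
          out$kappa_sync[row] <- max(k, 0)
        }
        if ("oscsync" %in% metrics) {
          cg <- new_correlogram(lam, L, bin_width, "normalized",
                                pair = c(c1, c2))
          out$kappa_oscsync[row] <-
            if (all(lam == 0)) 0 else kappa_oscsync(cg, f_min, f_max)
        }
      }
    }
  }
  out
}
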