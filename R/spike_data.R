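#' Electrode grid geometry
#'
#' Describes a planar multi-electrode array: one (x, y) position per channel,
#' the lattice spacing, and the set of dead (excluded) channels. The default
#' constructor lays channels out row-major on a regular `n_rows` x `n_cols`
#' lattice, matching a 4 x 4 Eckhorn-style matrix with 500 micrometre pitch.
#'
#' @param n_rows,n_cols lattice dimensions (ignored when `positions` given).
#' @param spacing lattice spacing `d_grid` in micrometres; must be positive.
#' @param dead_channels integer ids of non-functional channels.
#' @param positions optional data.frame with columns `channel`, `x`, `y`
#'   (micrometres) overriding the regular layout. Positions must be distinct.
#' @return an object of class `electrode_grid` with elements `positions`,
#'   `spacing`, `dead_channels`.
#' @examples
#' g <- electrode_grid(4, 4, spacing = 500, dead_channels = 13)
#' length(live_channels(g))  # 15
#' @export
electrode_grid <- function(n_rows = 4, n_cols = 4, spacing = 500,
                           dead_channels = integer(), positions = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive number")
  if (is.null(positions)) {
    positions <- data.frame(
      channel = seq_len(n_rows * n_cols),
      x = rep(seq_len(n_cols) - 1L, times = n_rows) * spacing,
      y = rep(seq_len(n_rows) - 1L, each = n_cols) * spacing
    )
  } else {
    need <- c("channel", "x", "y")
    if (!all(need %in% names(positions)))
      stop("'positions' must have columns channel, x, y")
    positions <- positions[order(positions$channel), need, drop = FALSE]
  }
  if (anyDuplicated(positions$channel))
    stop("duplicated channel ids in grid")
  if (anyDuplicated(positions[c("x", "y")]))
    stop("electrode positions must be distinct")
  dead_channels <- as.integer(dead_channels)
  if (!all(dead_channels %in% positions$channel))
    stop("dead_channels must be a subset of channel ids")
  structure(list(positions = positions, spacing = spacing,
                 dead_channels = sort(unique(dead_channels))),
            class = "electrode_grid")
}

#' @rdname electrode_grid
#' @param grid an `electrode_grid`.
#' @export
live_channels <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  setdiff(grid$positions$channel, grid$dead_channels)
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("electrode_grid: %d channels (%d dead), spacing %g um\n",
              nrow(x$positions), length(x$dead_channels), x$spacing))
  invisible(x)
}

#' Spike train of one channel in one trial
#'
#' @param times spike event times in seconds, non-negative, within
#'   `[0, duration]`; sorted on construction.
#' @param duration trial duration in seconds (analysis window).
#' @param channel,stimulus,repetition integer labels, may be `NA` for
#'   free-standing trains.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, duration, channel = NA_integer_,
                        stimulus = NA_integer_, repetition = NA_integer_) {
  times <- as.numeric(times)
  if (length(times) && (any(!is.finite(times)) || any(times < 0) ||
                        any(times > duration)))
    stop("spike times must lie within [0, duration]")
  if (!is.numeric(duration) || duration <= 0)
    stop("'duration' must be positive")
  structure(list(times = sort(times), duration = as.numeric(duration),
                 channel = as.integer(channel),
                 stimulus = as.integer(stimulus),
                 repetition = as.integer(repetition)),
            class = "spike_train")
}

#' Bin a spike train into a binary or count vector
#'
#' Bin `k` (0-based) covers the half-open interval `[k*bin_width,
#' (k+1)*bin_width)`; an event at exactly `t == duration` is placed in the
#' last bin. In binary mode multiple events per bin clip to 1. The default
#' 2 ms width matches the correlogram binning used throughout.
#'
#' @param train a [spike_train()].
#' @param bin_width bin width in seconds, default 0.002.
#' @param mode `"binary"` (0/1 per bin) or `"count"` (events per bin).
#' @return object of class `binned_train` with elements `values`,
#'   `bin_width`, `duration` and the train's labels.
#' @examples
#' tr <- spike_train(c(0.001, 0.0015, 0.005), duration = 0.008)
#' bin_spike_train(tr)$values  # 1 0 1 0
#' @export
bin_spike_train <- function(train, bin_width = 0.002,
                            mode = c("binary", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "spike_train"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a single positive number")
  n_bins <- as.integer(ceiling(train$duration / bin_width - 1e-9))
  n_bins <- max(n_bins, 1L)
  idx <- pmin(floor(train$times / bin_width), n_bins - 1L) + 1L
  values <- tabulate(idx, nbins = n_bins)
  if (mode == "binary") values <- pmin(values, 1L)
  structure(list(values = as.numeric(values), bin_width = bin_width,
                 duration = train$duration, mode = mode,
                 channel = train$channel, stimulus = train$stimulus,
                 repetition = train$repetition),
            class = "binned_train")
}

#' Multi-channel spike dataset
#'
#' Container for a whole experiment: spike times indexed by (channel,
#' stimulus, repetition), grid geometry, trial duration, per-repetition
#' phase labels and a stimulus catalogue.
#'
#' @param grid an [electrode_grid()].
#' @param spikes data.frame with columns `channel`, `stimulus`,
#'   `repetition`, `time_s` (one event per row).
#' @param duration common trial duration in seconds.
#' @param phases character vector of phase labels (`"warm"`,
#'   `"deactivation"`, `"rewarm"`, ...), one per repetition index.
#' @param stimuli data.frame cataloguing the stimulus conditions, with at
#'   least columns `stimulus` and `label`.
#' @return object of class `spike_dataset`.
#' @export
spike_dataset <- function(grid, spikes, duration, phases, stimuli) {
  stopifnot(inherits(grid, "electrode_grid"))
  need <- c("channel", "stimulus", "repetition", "time_s")
  if (!all(need %in% names(spikes)))
    stop("'spikes' must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(spikes$channel), live_channels(grid))
  if (length(bad))
    stop("spikes recorded on dead or unknown channel(s): ",
         paste(bad, collapse = ", "))
  if (any(spikes$time_s < 0) || any(spikes$time_s > duration))
    stop("spike times must lie within [0, duration]")
  if (!all(c("stimulus", "label") %in% names(stimuli)))
    stop("'stimuli' must have columns stimulus, label")
  phases <- as.character(phases)
  if (any(spikes$repetition > length(phases)))
    stop("repetition index exceeds the number of phase labels")
  structure(list(grid = grid,
                 spikes = spikes[order(spikes$channel, spikes$stimulus,
                                       spikes$repetition, spikes$time_s), ,
                                 drop = FALSE],
                 duration = as.numeric(duration),
                 phases = phases, stimuli = stimuli),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf(paste0("spike_dataset: %d live channels, %d stimuli, ",
                     "%d repetitions, %.3g s trials, %d events\n"),
              length(live_channels(x$grid)), nrow(x$stimuli),
              length(x$phases), x$duration, nrow(x$spikes)))
  cat(sprintf("phases: %s\n",
              paste(rle(x$phases)$values, collapse = " -> ")))
  invisible(x)
}

#' Extract one spike train from a dataset
#'
#' @param dataset a [spike_dataset()].
#' @param channel,stimulus,repetition indices of the wanted train.
#' @return a [spike_train()] (possibly with zero events).
#' @export
get_train <- function(dataset, channel, stimulus, repetition) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!channel %in% live_channels(dataset$grid))
    stop("channel ", channel, " is dead or unknown")
  s <- dataset$spikes
  sel <- s$channel == channel & s$stimulus == stimulus &
    s$repetition == repetition
  spike_train(s$time_s[sel], dataset$duration, channel, stimulus, repetition)
}

#' Read and write the spike-dataset container
#'
#' The container is a directory with three tab-separated files:
#' `grid.tsv` (columns `channel`, `x`, `y`, `dead` with `dead` in 0/1),
#' `spikes.tsv` (columns `channel`, `stimulus`, `repetition`, `time_s`, one
#' event per row) and `meta.tsv` (columns `record`, `id`, `value`; records
#' `duration` — trial length in seconds, `spacing` — grid pitch, `phase` —
#' phase label per repetition id, `stimulus` — catalogue label per stimulus
#' id). `write_dataset()` followed by `read_dataset()` reproduces the
#' dataset up to floating-point representation of event times.
#'
#' @param dataset a [spike_dataset()].
#' @param path directory to create/read.
#' @return `read_dataset()` returns a [spike_dataset()];
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spike_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- dataset$grid
  grid_tab <- data.frame(channel = g$positions$channel,
                         x = g$positions$x, y = g$positions$y,
                         dead = as.integer(g$positions$channel %in%
                                             g$dead_channels))
  tsv <- function(df, file)
    write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(grid_tab, "grid.tsv")
  tsv(dataset$spikes, "spikes.tsv")
  meta <- rbind(
    data.frame(record = "duration", id = 1L,
               value = format(dataset$duration, digits = 17)),
    data.frame(record = "spacing", id = 1L,
               value = format(g$spacing, digits = 17)),
    data.frame(record = "phase", id = seq_along(dataset$phases),
               value = dataset$phases),
    data.frame(record = "stimulus", id = dataset$stimuli$stimulus,
               value = dataset$stimuli$label)
  )
  tsv(meta, "meta.tsv")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  need_file <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("dataset container is missing ", f)
    read.delim(p, stringsAsFactors = FALSE)
  }
  grid_tab <- need_file("grid.tsv")
  spikes <- need_file("spikes.tsv")
  meta <- need_file("meta.tsv")
  for (spec in list(c("grid.tsv", "channel", "x", "y", "dead"),
                    c("spikes.tsv", "channel", "stimulus", "repetition",
                      "time_s"),
                    c("meta.tsv", "record", "id", "value"))) {
    tab <- switch(spec[1], grid.tsv = grid_tab, spikes.tsv = spikes,
                  meta.tsv = meta)
    missing_cols <- setdiff(spec[-1], names(tab))
    if (length(missing_cols))
      stop(spec[1], " is missing column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  pull <- function(rec) meta[meta$record == rec, , drop = FALSE]
  if (!nrow(pull("duration"))) stop("meta.tsv has no 'duration' record")
  if (!nrow(pull("phase"))) stop("meta.tsv has no 'phase' records")
  if (!nrow(pull("stimulus"))) stop("meta.tsv has no 'stimulus' records")
  spacing <- if (nrow(pull("spacing")))
    as.numeric(pull("spacing")$value[1]) else 1
  grid <- electrode_grid(
    spacing = spacing,
    dead_channels = grid_tab$channel[grid_tab$dead == 1],
    positions = grid_tab[c("channel", "x", "y")]
  )
  ph <- pull("phase")
  phases <- ph$value[order(as.integer(ph$id))]
  st <- pull("stimulus")
  stimuli <- data.frame(stimulus = as.integer(st$id), label = st$value)
  stimuli <- stimuli[order(stimuli$stimulus), , drop = FALSE]
  spike_dataset(grid, spikes, as.numeric(pull("duration")$value[1]),
                phases, stimuli)
}
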