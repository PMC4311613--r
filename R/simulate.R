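#' Simulate a tensor with known trilinear structure
#'
#' Builds `X = sum_f a_f (x) b_f (x) c_f + noise` from random loadings and
#' i.i.d. Gaussian noise whose standard deviation is a chosen fraction of
#' the signal's standard deviation. The ground-truth loadings are returned
#' in the same normalization [als_fit()] uses (unit-norm B and C columns,
#' magnitude in A, sign-fixed, ordered by contribution) and packaged as a
#' `parafac_model`, so [factor_match()] can score recovery directly.
#' Loadings are redrawn (bounded retries) until every pair of components
#' has combined congruence magnitude below `max_congruence`, keeping the
#' planted components well separated.
#'
#' @param dims integer vector `c(I, J, K)`.
#' @param rank number of planted components `R >= 1`.
#' @param noise_sd noise standard deviation relative to the signal SD
#'   (e.g. 0.1 = 10% noise); 0 gives an exactly rank-`R` tensor.
#' @param max_congruence separation bound on planted components, default
#'   0.9.
#' @param max_tries redraw budget for the separation constraint.
#' @param seed optional integer seed; the result is a pure function of
#'   the configuration and seed.
#' @return list: `tensor` (3-way array), `truth` (a `parafac_model`
#'   holding the planted loadings), `noise_sd_abs` (the absolute noise SD
#'   used).
#' @export
simulate_tensor <- function(dims, rank, noise_sd = 0.1,
                            max_congruence = 0.9, max_tries = 100,
                            seed = NULL) {
  stopifnot(length(dims) == 3L, all(dims >= 2), rank >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) matrix(runif(n * rank), n, rank)
  sep_ok <- function(a, b, cc) {
    if (rank == 1L) return(TRUE)
    cong <- function(m) {
      nm <- sweep(m, 2, sqrt(colSums(m^2)), "/")
      crossprod(nm)
    }
    comb <- cong(a) * cong(b) * cong(cc)
    max(abs(comb[upper.tri(comb)])) < max_congruence
  }
  for (try in seq_len(max_tries)) {
    a <- draw(dims[1]); b <- draw(dims[2]); cc <- draw(dims[3])
    if (sep_ok(a, b, cc)) break
    if (try == max_tries)
      stop("could not draw loadings with the requested separation")
  }
  signal <- fold(a %*% t(khatri_rao(cc, b)), 1, dims)
  sigma <- noise_sd * sd(as.vector(signal))
  x <- signal + array(rnorm(prod(dims), 0, sigma), dims)
  truth <- normalize_parafac(structure(
    list(n_components = rank, A = a, B = b, C = cc, dims = dims,
         labels = NULL),
    class = "parafac_model"))
  list(tensor = x, truth = truth, noise_sd_abs = sigma)
}

#' Simulate a multi-electrode spike experiment with planted synchrony
#'
#' Emulates the structure of a grating-stimulation experiment on a planar
#' electrode array: a 4 x 4 grid (500 um pitch, one dead channel by
#' default), 8 stimulus conditions (4 grating orientations x 2 motion
#' directions), 8 s trials (2 s gray screen, 2 s static grating, 4 s
#' moving grating), and 63 repetitions per stimulus organized as 3 cycles
#' x 7 repetitions for each of three phases — warm (repetitions 1-21),
#' deactivation (22-42), rewarm (43-63).
#'
#' Every live channel fires homogeneous Poisson background spikes.
#' Pairwise synchrony is planted through "assemblies": for each assembly,
#' each within-assembly channel pair receives a Poisson mother train of
#' shared events, inserted into both channels with independent Gaussian
#' timing jitter. The mother rate is `injection_rate * stimulus weight *
#' phase multiplier`, so the synchrony a jitter-corrected correlogram
#' detects has exactly trilinear (pair x stimulus x phase) structure; a
#' deactivation multiplier below 1 plants the synchrony dip in
#' repetitions 22-42. Optionally, a common sinusoidal rate modulation
#' (default 40 Hz) with a trial-shared random phase is applied to a
#' designated channel group, giving those pairs oscillatory synchrony in
#' the gamma band.
#'
#' @param grid an [electrode_grid()]; default 4 x 4, 500 um, channel 13
#'   dead.
#' @param orientations,directions grating parameters whose crossing forms
#'   the stimulus catalogue (defaults: 0/45/90/135 degrees, two motion
#'   directions).
#' @param cycles_per_phase,reps_per_cycle repetitions are
#'   `3 * cycles_per_phase * reps_per_cycle` in total (default 3 and 7:
#'   63 repetitions, 21 per phase).
#' @param durations named numeric `c(gray=, static=, moving=)` in seconds;
#'   their sum is the trial duration (default 8 s).
#' @param background_rate Poisson background rate per channel (Hz),
#'   default 20.
#' @param epoch_rate_factors multiplies the background rate in the gray /
#'   static / moving epochs (default `c(1, 1, 1)`: stationary background).
#' @param assemblies list of assemblies, each a list with `channels`
#'   (live channel ids) and either `preferred` (stimulus index; weights
#'   become 1 for it, `other_direction_weight` for the same orientation
#'   moving oppositely, `off_weight` elsewhere) or an explicit
#'   `stimulus_weights` vector, plus optionally `phase_multipliers`
#'   overriding the global ones. Default: three overlapping 6-channel
#'   assemblies with distinct preferred stimuli and distinct deactivation
#'   sensitivities (derived from the global `phase_multipliers`), so the
#'   planted trilinear model is identifiable and the pairwise synchrony
#'   pattern is dense.
#' @param injection_rate mother-train rate (Hz) at stimulus weight 1 and
#'   phase multiplier 1, default 15 — strong shared drive of the order of
#'   the background rate, as in gamma-synchronized multi-unit activity,
#'   giving assembly pairs the prominent correlogram peaks the analysis
#'   is designed around.
#' @param phase_multipliers named numeric over the three phases, default
#'   `c(warm = 1, deactivation = 0.3, rewarm = 1)`.
#' @param other_direction_weight,off_weight stimulus-tuning weights used
#'   when an assembly gives `preferred` (defaults 0.5 and 0.1).
#' @param jitter_sd SD of the per-channel timing jitter on injected
#'   events (s), default 0.001 (inside the 5 ms peak window, wider than
#'   one 2 ms bin).
#' @param osc_freq,osc_depth,osc_channels common oscillatory modulation:
#'   frequency (Hz, default 40), modulation depth in `[0, 1]` (default 0
#'   = off), and the co-modulated channel group.
#' @param seed optional integer seed; generation is a pure function of
#'   configuration and seed.
#' @return a [spike_dataset()]; attribute `ground_truth` carries the
#'   planted loadings as a `parafac_model` (`truth`), the per-phase
#'   multipliers, and the assembly definitions.
#' @export
simulate_experiment <- function(
    grid = electrode_grid(4, 4, 500, dead_channels = 13),
    orientations = c(0, 45, 90, 135), directions = c("fwd", "rev"),
    cycles_per_phase = 3, reps_per_cycle = 7,
    durations = c(gray = 2, static = 2, moving = 4),
    background_rate = 20, epoch_rate_factors = c(1, 1, 1),
    assemblies = NULL, injection_rate = 15,
    phase_multipliers = c(warm = 1, deactivation = 0.3, rewarm = 1),
    other_direction_weight = 0.5, off_weight = 0.1,
    jitter_sd = 0.001, osc_freq = 40, osc_depth = 0,
    osc_channels = integer(), seed = NULL) {
  stopifnot(inherits(grid, "electrode_grid"),
            background_rate >= 0, injection_rate >= 0,
            all(phase_multipliers >= 0), jitter_sd >= 0,
            osc_depth >= 0, osc_depth <= 1,
            length(durations) == 3L, all(durations >= 0),
            length(epoch_rate_factors) == 3L, all(epoch_rate_factors >= 0))
  if (!is.null(seed)) set.seed(seed)
  live <- live_channels(grid)
  stopifnot(all(osc_channels %in% live))
  if (injection_rate > background_rate && background_rate > 0)
    warning("injection rate exceeds the background rate; ",
            "injected coincidences will dominate the trains")
  trial_t <- sum(durations)
  n_stim <- length(orientations) * length(directions)
  stimuli <- data.frame(
    stimulus = seq_len(n_stim),
    label = paste0("ori", rep(orientations, each = length(directions)),
                   "_", rep(directions, length(orientations))),
    orientation = rep(orientations, each = length(directions)),
    direction = rep(directions, length(orientations)))
  phase_names <- c("warm", "deactivation", "rewarm")
  reps_per_phase <- cycles_per_phase * reps_per_cycle
  n_rep <- 3L * reps_per_phase
  phases <- rep(phase_names, each = reps_per_phase)
  if (is.null(assemblies)) {
    # Three overlapping 6-channel assemblies with distinct stimulus
    # preferences AND distinct deactivation sensitivities. Distinct
    # phase profiles keep the C factor at full k-rank so the planted
    # decomposition satisfies Kruskal's uniqueness condition (identical
    # profiles would leave rotational freedom across components and an
    # unrecoverable model); overlapping membership gives the dense
    # pairwise synchrony pattern typical of cortical recordings. A pair
    # driven by two assemblies sums their mother rates, which preserves
    # exact trilinearity of the planted rate structure.
    pool <- list(c(1, 2, 5, 6, 9, 10), c(7, 8, 11, 12, 15, 16),
                 c(3, 4, 7, 8, 10, 14))
    pool <- lapply(pool, function(ch) intersect(ch, live))
    g <- phase_multipliers
    blend <- function(sens, rewarm_fac)
      c(warm = unname(g["warm"]),
        deactivation = unname(1 - (1 - g["deactivation"]) * sens),
        rewarm = unname(g["rewarm"] * rewarm_fac))
    assemblies <- list(
      list(channels = pool[[1]], preferred = 1L,
           phase_multipliers = blend(1.0, 1.0)),
      list(channels = pool[[2]], preferred = 4L,
           phase_multipliers = blend(0.6, 0.9)),
      list(channels = pool[[3]], preferred = 6L,
           phase_multipliers = blend(0.25, 1.0)))
  }
  for (a in assemblies) {
    if (!all(a$channels %in% live))
      stop("assembly references a dead or unknown channel")
  }
  # --- background spikes, per epoch (vectorized over all trials) ------
  cell <- expand.grid(channel = live, stimulus = stimuli$stimulus,
                      repetition = seq_len(n_rep),
                      KEEP.OUT.ATTRS = FALSE)
  epoch_offsets <- c(0, cumsum(durations))[1:3]
  ev_ch <- ev_st <- ev_rp <- integer(0)
  ev_t <- numeric(0)
  osc_gain <- if (length(osc_channels) && osc_depth > 0) 1 + osc_depth else 1
  trial_phase <- matrix(runif(n_stim * n_rep, 0, 2 * pi), n_stim, n_rep)
  for (e in 1:3) {
    if (durations[e] == 0 || background_rate == 0 ||
        epoch_rate_factors[e] == 0) next
    lam <- background_rate * epoch_rate_factors[e] * durations[e]
    lam_cell <- ifelse(cell$channel %in% osc_channels,
                       lam * osc_gain, lam)
    counts <- rpois(nrow(cell), lam_cell)
    tot <- sum(counts)
    if (tot == 0) next
    t_e <- runif(tot, 0, durations[e]) + epoch_offsets[e]
    ch_e <- rep(cell$channel, counts)
    st_e <- rep(cell$stimulus, counts)
    rp_e <- rep(cell$repetition, counts)
    if (osc_gain > 1) {
      is_osc <- ch_e %in% osc_channels
      if (any(is_osc)) {
        phi <- trial_phase[cbind(st_e[is_osc], rp_e[is_osc])]
        keep_p <- (1 + osc_depth *
                     sin(2 * pi * osc_freq * t_e[is_osc] + phi)) / osc_gain
        keep <- !is_osc
        keep[is_osc] <- runif(sum(is_osc)) < keep_p
      } else keep <- rep(TRUE, tot)
      t_e <- t_e[keep]; ch_e <- ch_e[keep]
      st_e <- st_e[keep]; rp_e <- rp_e[keep]
    }
    ev_t <- c(ev_t, t_e); ev_ch <- c(ev_ch, ch_e)
    ev_st <- c(ev_st, st_e); ev_rp <- c(ev_rp, rp_e)
  }
  # --- injected coincidences: one mother train per (pair, stim, rep) --
  mult_of_rep <- phase_multipliers[phases]
  stim_weights_of <- function(a) {
    if (!is.null(a$stimulus_weights)) {
      stopifnot(length(a$stimulus_weights) == n_stim)
      return(a$stimulus_weights)
    }
    w <- rep(off_weight, n_stim)
    pref <- a$preferred
    w[pref] <- 1
    twin <- which(stimuli$orientation == stimuli$orientation[pref] &
                    stimuli$stimulus != pref)
    w[twin] <- other_direction_weight
    w
  }
  pairs <- enumerate_pairs(grid)
  a_true <- matrix(0, nrow(pairs), length(assemblies),
                   dimnames = list(pairs$pair, NULL))
  b_true <- matrix(0, n_stim, length(assemblies))
  c_true <- matrix(0, n_rep, length(assemblies))
  for (ai in seq_along(assemblies)) {
    a <- assemblies[[ai]]
    w <- stim_weights_of(a)
    mult <- if (is.null(a$phase_multipliers)) mult_of_rep
            else a$phase_multipliers[phases]
    b_true[, ai] <- w
    c_true[, ai] <- mult
    if (length(a$channels) < 2L) next
    cmb <- combn(sort(a$channels), 2L)
    for (p in seq_len(ncol(cmb))) {
      c1 <- cmb[1, p]; c2 <- cmb[2, p]
      a_true[pairs$pair == paste(c1, c2, sep = "-"), ai] <- 1
      lam <- injection_rate * trial_t * outer(w, mult)  # n_stim x n_rep
      counts <- rpois(length(lam), as.vector(lam))
      tot <- sum(counts)
      if (tot == 0) next
      cell_st <- rep(rep(seq_len(n_stim), n_rep), counts)
      cell_rp <- rep(rep(seq_len(n_rep), each = n_stim), counts)
      mother <- runif(tot, 0, trial_t)
      for (chn in c(c1, c2)) {
        tt <- mother + rnorm(tot, 0, jitter_sd)
        tt <- pmin(pmax(tt, 0), trial_t)
        ev_t <- c(ev_t, tt)
        ev_ch <- c(ev_ch, rep(chn, tot))
        ev_st <- c(ev_st, cell_st)
        ev_rp <- c(ev_rp, cell_rp)
      }
    }
  }
  spikes <- data.frame(channel = ev_ch, stimulus = ev_st,
                       repetition = ev_rp, time_s = ev_t)
  ds <- spike_dataset(grid, spikes, trial_t, phases, stimuli)
  truth <- normalize_parafac(structure(
    list(n_components = length(assemblies), A = a_true, B = b_true,
         C = c_true, dims = c(nrow(pairs), n_stim, n_rep),
         labels = list(pairs$pair, as.character(seq_len(n_stim)),
                       as.character(seq_len(n_rep)))),
    class = "parafac_model"))
  attr(ds, "ground_truth") <- list(
    truth = truth, assemblies = assemblies,
    phase_multipliers = phase_multipliers,
    injection_rate = injection_rate, jitter_sd = jitter_sd,
    osc_freq = osc_freq, osc_depth = osc_depth,
    osc_channels = osc_channels)
  ds
}
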