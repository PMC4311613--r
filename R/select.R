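#' Choose the number of PARAFAC components
#'
#' Implements the two-part selection heuristic for the component count.
#' Models with `F = 1 .. f_max` are fitted (multi-start ALS each). First,
#' the scree rule bounds the candidates: component `F` counts as a
#' significant residual decrease while it removes more of the remaining
#' residual sum of squares than an extra component could extract from
#' unstructured noise. That noise benchmark is the random-matrix
#' top-singular-value fraction `min_n (sqrt(d_n) + sqrt(IJK/d_n))^2 /
#' (IJK)` — the share of a pure-noise tensor's sum of squares a best
#' rank-one term can absorb, in the spirit of parallel analysis — and it
#' adapts to the tensor's dimensions with no tuned constant. A fixed
#' fraction can be supplied via `rel_gain_tol` instead; `min_gain` is an
#' absolute percentage-point floor for the noiseless edge case.
#' Second, among the candidates, the chosen `F` is the largest whose
#' best-of-starts model has maximum absolute off-diagonal *combined*
#' congruence at or below `congruence_threshold` — the model explaining
#' the most variance without any two components being correlated.
#' `F = 1` is always admissible; when no candidate `F >= 2` is, the
#' report carries `all_correlated = TRUE`. A model with a zero-norm
#' (dead) component counts as inadmissible. The full trace (variance,
#' gain, congruence, both admissibility flags) is reported.
#'
#' @param x 3-way numeric array (typically a centered `synchrony_tensor`).
#' @param f_max largest component count tried, default 6.
#' @param congruence_threshold admissibility bound on `max |combined
#'   off-diagonal congruence|`, default 0.85.
#' @param rel_gain_tol minimum fraction of the remaining residual a
#'   further component must remove to count as significant; `NULL`
#'   (default) uses the adaptive noise benchmark described above.
#' @param min_gain absolute explained-variance floor (percentage points)
#'   on the same step, default 0.01.
#' @param n_starts,tol,max_iter,seed passed to [als_fit()]; each candidate
#'   F gets a seed derived deterministically from `seed`, so the whole
#'   selection is reproducible.
#' @return object of class `selection_report`: `trace` (data.frame with
#'   columns `f`, `explained_variance`, `ev_gain`, `max_congruence`,
#'   `candidate`, `admissible`), `chosen_f`, `all_correlated`, `models`
#'   (one `parafac_model` per fitted candidate), `rationale`.
#' @export
select_components <- function(x, f_max = 6, congruence_threshold = 0.85,
                              rel_gain_tol = NULL, min_gain = 0.01,
                              n_starts = 10, tol = 1e-8,
                              max_iter = 2000, seed = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  f_max <- as.integer(f_max)
  if (f_max < 1L) stop("'f_max' must be >= 1")
  fmax_feasible <- min(dim(x)[1] * dim(x)[2], dim(x)[1] * dim(x)[3],
                       dim(x)[2] * dim(x)[3])
  f_max <- min(f_max, fmax_feasible)
  if (!is.null(seed)) set.seed(seed)
  f_seeds <- sample.int(.Machine$integer.max, f_max)
  models <- vector("list", f_max)
  ev <- maxcong <- numeric(f_max)
  for (f in seq_len(f_max)) {
    models[[f]] <- als_fit(x, f, n_starts = n_starts, tol = tol,
                           max_iter = max_iter, seed = f_seeds[f])
    ev[f] <- models[[f]]$explained_variance
    maxcong[f] <- if (f == 1L) 0 else tryCatch({
      cc <- component_congruence(models[[f]])$combined
      max(abs(cc[upper.tri(cc)]))
    }, error = function(e) Inf)  # zero-norm (dead) component
  }
  gain <- c(ev[1L], diff(ev))
  resid_before <- 100 - c(0, ev[-f_max])  # residual left to the F-1 model
  if (is.null(rel_gain_tol)) {
    d <- dim(x); n <- prod(d)
    rel_gain_tol <- min((sqrt(d) + sqrt(n / d))^2 / n)
  }
  # scree rule: keep the prefix of F values whose every step removes a
  # significant share of the remaining residual
  significant <- c(TRUE,
                   (gain >= pmax(rel_gain_tol * resid_before, min_gain))[-1L])
  f_stop <- if (all(significant)) f_max else min(which(!significant)) - 1L
  candidate <- seq_len(f_max) <= f_stop
  uncorrelated <- maxcong <= congruence_threshold
  admissible <- candidate & uncorrelated
  chosen <- max(which(admissible))
  all_correlated <- f_stop >= 2L && !any(uncorrelated[2:f_stop])
  trace <- data.frame(f = seq_len(f_max), explained_variance = ev,
                      ev_gain = gain, max_congruence = maxcong,
                      candidate = candidate, admissible = admissible)
  rationale <- sprintf(
    paste0("residual decrease stays significant (each component removes ",
           ">= %.0f%% of the remaining residual) up to F = %d; largest ",
           "such F with max |combined off-diagonal congruence| <= %.2f ",
           "is %d (%.2f%% explained variance)%s"),
    100 * rel_gain_tol, f_stop, congruence_threshold, chosen, ev[chosen],
    if (all_correlated) "; every candidate F >= 2 had correlated components"
    else "")
  structure(list(trace = trace, chosen_f = chosen,
                 all_correlated = all_correlated, models = models,
                 congruence_threshold = congruence_threshold,
                 rel_gain_tol = rel_gain_tol, min_gain = min_gain,
                 rationale = rationale),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("selection_report: chosen F =", x$chosen_f, "\n")
  cat(x$rationale, "\n")
  print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a selection report as a tab-separated trace
#'
#' @param report a `selection_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_selection <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# chosen_f: %d", report$chosen_f),
               sprintf("# congruence_threshold: %g",
                       report$congruence_threshold),
               sprintf("# rel_gain_tol: %g", report$rel_gain_tol),
               sprintf("# min_gain: %g", report$min_gain),
               sprintf("# rationale: %s", report$rationale)), con)
  write.table(report$trace, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
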