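#' Congruence-based alignment and factor-match score of two models
#'
#' Components of two fitted PARAFAC models are matched by a greedy
#' assignment on their combined congruence (product over the compared
#' modes of the cosine between loading columns), taking the
#' largest-magnitude remaining entry first. After alignment the score per
#' component is that product, in `[-1, 1]`; identical aligned models score
#' 1. The summary score is the mean over components. Models fitted to
#' different repetition subsets are compared on the shared `A` and `B`
#' modes only; in that case each component's score is sign-matched (its
#' absolute value is taken), because a sign flip in one compared mode can
#' be compensated by a flip in an uncompared mode without changing the
#' reconstruction, so two-mode scores are only defined up to sign. The
#' full three-mode product is invariant under such compensating flips and
#' keeps its sign.
#'
#' @param model1,model2 `parafac_model`s with equal `n_components`.
#' @param modes character subset of `c("A", "B", "C")` entering the
#'   product, default all three.
#' @return list: `score` (mean over components), `per_component`,
#'   `permutation` (component of `model2` matched to each of `model1`),
#'   `per_mode` (named list of per-component cosines by mode).
#' @export
factor_match <- function(model1, model2, modes = c("A", "B", "C")) {
  stopifnot(inherits(model1, "parafac_model"),
            inherits(model2, "parafac_model"))
  if (model1$n_components != model2$n_components)
    stop("models have different numbers of components")
  modes <- match.arg(modes, c("A", "B", "C"), several.ok = TRUE)
  f <- model1$n_components
  cosines <- lapply(modes, function(m) {
    u <- model1[[m]]; v <- model2[[m]]
    if (nrow(u) != nrow(v))
      stop("mode ", m, " has different lengths in the two models")
    nu <- sqrt(colSums(u^2)); nv <- sqrt(colSums(v^2))
    if (any(nu == 0) || any(nv == 0)) stop("zero-norm component column")
    crossprod(sweep(u, 2, nu, "/"), sweep(v, 2, nv, "/"))
  })
  names(cosines) <- modes
  combined <- Reduce(`*`, cosines)
  perm <- integer(f)
  open_r <- seq_len(f); open_c <- seq_len(f)
  for (step in seq_len(f)) {
    sub <- combined[open_r, open_c, drop = FALSE]
    hit <- which(abs(sub) == max(abs(sub)), arr.ind = TRUE)[1L, ]
    perm[open_r[hit[1L]]] <- open_c[hit[2L]]
    open_r <- open_r[-hit[1L]]; open_c <- open_c[-hit[2L]]
  }
  per_component <- combined[cbind(seq_len(f), perm)]
  if (!all(c("A", "B", "C") %in% modes))
    per_component <- abs(per_component)
  per_mode <- lapply(cosines, function(m) m[cbind(seq_len(f), perm)])
  list(score = mean(per_component), per_component = per_component,
       permutation = perm, per_mode = per_mode)
}

#' Split-half validation of a PARAFAC decomposition
#'
#' Partitions the tensor along the repetition mode into odd- and
#' even-indexed slices (by repetition index, so warm/deactivation/rewarm
#' phases stay balanced across halves), fits an independent model on each,
#' aligns components, and scores their similarity on the shared pair and
#' stimulus modes. Similar loadings and similar explained variances in
#' both halves indicate a stable, applicable model.
#'
#' @param x 3-way numeric array with repetition as the third mode
#'   (length >= 4).
#' @param n_components components `F` for both half-fits.
#' @param n_starts,tol,max_iter,seed passed to [als_fit()] (each half gets
#'   a distinct seed derived from `seed`).
#' @return object of class `split_half_result`: `model_odd`,
#'   `model_even`, `match` (a [factor_match()] result on modes A and B),
#'   `explained_variance` (named vector, both halves), `odd_reps`,
#'   `even_reps`.
#' @export
split_half <- function(x, n_components, n_starts = 10, tol = 1e-8,
                       max_iter = 2000, seed = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  k <- dim(x)[3]
  if (k < 4L) stop("need at least 4 repetitions to split")
  odd <- seq(1L, k, by = 2L)
  even <- seq(2L, k, by = 2L)
  if (!is.null(seed)) set.seed(seed)
  half_seeds <- sample.int(.Machine$integer.max, 2L)
  fit_half <- function(idx, s)
    als_fit(x[, , idx, drop = FALSE], n_components, n_starts = n_starts,
            tol = tol, max_iter = max_iter, seed = s)
  model_odd <- fit_half(odd, half_seeds[1L])
  model_even <- fit_half(even, half_seeds[2L])
  match <- factor_match(model_odd, model_even, modes = c("A", "B"))
  structure(list(model_odd = model_odd, model_even = model_even,
                 match = match,
                 explained_variance = c(
                   odd = model_odd$explained_variance,
                   even = model_even$explained_variance),
                 odd_reps = odd, even_reps = even),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf(paste0("split_half_result: F = %d; explained variance odd ",
                     "%.2f%% / even %.2f%%; pair+stimulus factor match ",
                     "%.4f\n"),
              x$model_odd$n_components, x$explained_variance["odd"],
              x$explained_variance["even"], x$match$score))
  invisible(x)
}

#' Residual-bootstrap sensitivity of a PARAFAC solution
#'
#' Probes how sensitive the fitted solution is to the distribution of the
#' model error. Residuals `e = x - xhat` are computed once; then two sets
#' of `n_reps` surrogate tensors are built — one adding errors resampled
#' with replacement from the empirical residual distribution, one adding
#' draws from a Gaussian fitted to it (`Normal(mean(e), sd(e))`) — each
#' refit with the same `F`, and every refit is scored against the baseline
#' model by [factor_match()] over all three modes. Similar score
#' distributions for the two sets indicate insensitivity to
#' non-Gaussianity of the errors.
#'
#' By default errors are added to the model reconstruction `xhat`
#' (parametric bootstrap: signal + fresh noise); `mode = "literal"` adds
#' them to the original data instead, which stacks new noise on top of the
#' residuals already present.
#'
#' @param x 3-way numeric array the baseline was fitted on.
#' @param model baseline `parafac_model` fitted on `x`.
#' @param n_reps replicates per error set, at least 2 (default 50).
#' @param seed integer seed; the whole procedure is reproducible given it.
#' @param mode `"parametric"` (default) or `"literal"`, see above.
#' @param n_starts random starts per refit (default 5; refits are many, so
#'   fewer starts than a headline fit).
#' @param tol,max_iter passed to [als_fit()].
#' @return object of class `bootstrap_result`: `scores_empirical`,
#'   `scores_gaussian` (length-`n_reps` factor-match scores), `residual_sd`,
#'   `residual_mean`, `mode`, `n_reps`.
#' @export
residual_bootstrap <- function(x, model, n_reps = 50, seed = NULL,
                               mode = c("parametric", "literal"),
                               n_starts = 5, tol = 1e-8, max_iter = 2000) {
  mode <- match.arg(mode)
  stopifnot(is.array(x), inherits(model, "parafac_model"))
  if (!identical(dim(x), model$dims)) stop("dimension mismatch")
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("'n_reps' must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  xhat <- reconstruct(model)
  resid <- as.vector(x - xhat)
  base_arr <- if (mode == "parametric") xhat else x
  refit_score <- function(err) {
    surrogate <- base_arr + array(err, dim = dim(x))
    refit <- als_fit(surrogate, model$n_components, n_starts = n_starts,
                     tol = tol, max_iter = max_iter,
                     seed = sample.int(.Machine$integer.max, 1L))
    factor_match(model, refit)$score
  }
  scores_emp <- vapply(seq_len(n_reps), function(i)
    refit_score(sample(resid, length(resid), replace = TRUE)), numeric(1))
  scores_gau <- vapply(seq_len(n_reps), function(i)
    refit_score(rnorm(length(resid), mean(resid), sd(resid))), numeric(1))
  structure(list(scores_empirical = scores_emp,
                 scores_gaussian = scores_gau,
                 residual_mean = mean(resid), residual_sd = sd(resid),
                 mode = mode, n_reps = n_reps),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(paste0("bootstrap_result (%s, %d reps): factor match ",
                     "empirical %.4f (sd %.4f) vs gaussian %.4f (sd ",
                     "%.4f)\n"),
              x$mode, x$n_reps,
              mean(x$scores_empirical), sd(x$scores_empirical),
              mean(x$scores_gaussian), sd(x$scores_gaussian)))
  invisible(x)
}
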