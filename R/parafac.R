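#' Fit a PARAFAC (canonical polyadic) model by alternating least squares
#'
#' Models a three-way array as a sum of `F` rank-one terms,
#' \eqn{x_{ijk} \approx \sum_f a_{if} b_{jf} c_{kf}}, with loading matrices
#' `A` (I x F, pairs), `B` (J x F, stimuli), `C` (K x F, repetitions). The
#' three conditional least-squares updates (A, then B, then C) are iterated
#' until the relative change in residual sum of squares falls below `tol`
#' or `max_iter` is reached; the residual is non-increasing across
#' iterations. Several random starts are run and the best-fitting kept,
#' since ALS can stop in local optima.
#'
#' The returned model is normalized for comparability across runs: columns
#' of `B` and `C` have unit norm with all magnitude absorbed into `A`, the
#' largest-magnitude entry of each `B` and `C` column is positive (sign
#' flips absorbed into `A`), and components are ordered by explained-sum-
#' of-squares contribution, descending. The reconstruction is invariant
#' under this normalization. Rank-deficient conditional systems are solved
#' by pseudoinverse with a warning. A warning is also issued when two
#' components show combined congruence below -0.85, the classic signature
#' of a degenerate PARAFAC solution.
#'
#' @param x 3-way numeric array (typically a `synchrony_tensor`, centered).
#' @param n_components number of components `F` (>= 1).
#' @param n_starts independent random initializations, default 10.
#' @param tol relative change in residual sum of squares declaring
#'   convergence, default 1e-8.
#' @param max_iter iteration cap per start, default 2000.
#' @param seed optional integer seed making the fit reproducible.
#' @return object of class `parafac_model`: `A`, `B`, `C`,
#'   `n_components`, `explained_variance` (percent), `sse`, `iterations`,
#'   `converged`, `fit_trace` (residual per iteration, best start),
#'   `start_fits` (explained variance of every start, with best and median
#'   summarized), `dims`, `labels`, `seed`.
#' @seealso [reconstruct()], [explained_variance()],
#'   [component_congruence()], [select_components()]
#' @export
als_fit <- function(x, n_components, n_starts = 10, tol = 1e-8,
                    max_iter = 2000, seed = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (!all(is.finite(x))) stop("input tensor contains non-finite values")
  dims <- dim(x)
  f <- as.integer(n_components)
  if (f < 1L) stop("'n_components' must be >= 1")
  fmax <- min(dims[1] * dims[2], dims[1] * dims[3], dims[2] * dims[3])
  if (f > fmax)
    stop("'n_components' exceeds the feasible rank for these dimensions")
  if (!is.null(seed)) set.seed(seed)
  start_seeds <- sample.int(.Machine$integer.max, n_starts)
  xmat <- lapply(1:3, function(m) unfold(x, m))
  ssx <- sum(x^2)
  if (ssx == 0) stop("input tensor is identically zero")
  best <- NULL
  start_ev <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(start_seeds[s])
    run <- als_run(xmat, dims, f, tol, max_iter, ssx)
    start_ev[s] <- 100 * (1 - run$sse / ssx)
    if (is.null(best) || run$sse < best$sse) best <- run
  }
  model <- structure(
    list(n_components = f, A = best$A, B = best$B, C = best$C,
         explained_variance = 100 * (1 - best$sse / ssx),
         sse = best$sse, iterations = best$iterations,
         converged = best$converged, fit_trace = best$trace,
         start_fits = list(all = start_ev, best = max(start_ev),
                           median = median(start_ev)),
         dims = dims, labels = dimnames(x), seed = seed),
    class = "parafac_model")
  model <- normalize_parafac(model)
  if (f >= 2L) {
    cc <- component_congruence(model)$combined
    if (any(cc[upper.tri(cc)] < -0.85))
      warning("combined congruence < -0.85: possible degenerate solution")
  }
  model
}

# One ALS run from a fresh uniform random init. xmat: list of the three
# unfoldings; returns loadings, residual trace, convergence info. The
# residual after the C update comes free from the normal equations:
# ||X - Xhat||^2 = ||X||^2 - 2 <C, M> + <C'C, G> with M = X3 (B (.) A)
# and G = (B'B) * (A'A), both already computed for that update.
als_run <- function(xmat, dims, f, tol, max_iter, ssx) {
  a <- matrix(runif(dims[1] * f), dims[1], f)
  b <- matrix(runif(dims[2] * f), dims[2], f)
  cc <- matrix(runif(dims[3] * f), dims[3], f)
  ls_solve <- function(g, m) {
    t(tryCatch(solve(g, t(m)),
               error = function(e) {
                 warning("rank-deficient ALS system; using pseudoinverse",
                         call. = FALSE)
                 MASS::ginv(g) %*% t(m)
               }))
  }
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a <- ls_solve(crossprod(cc) * crossprod(b),
                  xmat[[1]] %*% khatri_rao(cc, b))
    b <- ls_solve(crossprod(cc) * crossprod(a),
                  xmat[[2]] %*% khatri_rao(cc, a))
    g <- crossprod(b) * crossprod(a)
    m <- xmat[[3]] %*% khatri_rao(b, a)
    cc <- ls_solve(g, m)
    cur <- max(ssx - 2 * sum(cc * m) + sum(crossprod(cc) * g), 0)
    trace[it] <- cur
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, 1e-300)) {
      converged <- TRUE
      prev <- cur
      break
    }
    prev <- cur
  }
  list(A = a, B = b, C = cc, sse = prev, iterations = it,
       converged = converged, trace = trace[seq_len(it)])
}

# Columnwise Kronecker (Khatri-Rao) product: column f is kron(u[,f], v[,f]).
khatri_rao <- function(u, v) {
  stopifnot(ncol(v) == ncol(u))
  u[rep(seq_len(nrow(u)), each = nrow(v)), , drop = FALSE] *
    v[rep.int(seq_len(nrow(v)), nrow(u)), , drop = FALSE]
}

# Unit-norm B and C columns, magnitude and sign into A, components ordered
# by contribution (|a_f| with B, C unit norm). Reconstruction-invariant.
normalize_parafac <- function(model) {
  a <- model$A; b <- model$B; cc <- model$C
  for (j in seq_len(ncol(a))) {
    nb <- sqrt(sum(b[, j]^2)); nc <- sqrt(sum(cc[, j]^2))
    if (nb > 0) b[, j] <- b[, j] / nb
    if (nc > 0) cc[, j] <- cc[, j] / nc
    a[, j] <- a[, j] * nb * nc
    sb <- sign(b[which.max(abs(b[, j])), j])
    sc <- sign(cc[which.max(abs(cc[, j])), j])
    if (sb == 0) sb <- 1
    if (sc == 0) sc <- 1
    b[, j] <- b[, j] * sb
    cc[, j] <- cc[, j] * sc
    a[, j] <- a[, j] * sb * sc
  }
  ord <- order(colSums(a^2), decreasing = TRUE)
  model$A <- a[, ord, drop = FALSE]
  model$B <- b[, ord, drop = FALSE]
  model$C <- cc[, ord, drop = FALSE]
  if (!is.null(model$labels)) {
    rownames(model$A) <- model$labels[[1]]
    rownames(model$B) <- model$labels[[2]]
    rownames(model$C) <- model$labels[[3]]
  }
  model
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf(paste0("parafac_model: F = %d on [%s], explained variance ",
                     "%.2f%%, %d iterations (%s)\n"),
              x$n_components, paste(x$dims, collapse = " x "),
              x$explained_variance, x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Reconstruct the fitted tensor from a PARAFAC model
#'
#' \eqn{\hat x_{ijk} = \sum_f a_{if} b_{jf} c_{kf}}.
#'
#' @param model a `parafac_model`.
#' @return 3-way numeric array of the model's dimensions.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  fold(model$A %*% t(khatri_rao(model$C, model$B)), 1, model$dims,
       dn = model$labels)
}

#' Explained variance of a PARAFAC model
#'
#' `100 * (1 - ||X - Xhat||^2 / ||X||^2)`, the percentage of the tensor's
#' sum of squares captured by the model.
#'
#' @param model a `parafac_model`.
#' @param x the data tensor the model was (or is to be) evaluated on.
#' @return percent, at most 100.
#' @export
explained_variance <- function(model, x) {
  stopifnot(inherits(model, "parafac_model"), is.array(x))
  if (!identical(dim(x), model$dims)) stop("dimension mismatch")
  ssx <- sum(x^2)
  if (ssx == 0) stop("zero-norm tensor: explained variance undefined")
  100 * (1 - sum((x - reconstruct(model))^2) / ssx)
}

#' Component congruence (Tucker congruence) of a PARAFAC model
#'
#' Cosine similarity between every pair of component columns, per mode,
#' and the elementwise product across the three modes ("combined"). The
#' combined off-diagonal is the operational measure of "correlated
#' components" used for rank selection and degeneracy detection: identical
#' components give 1, sign-opposed degenerate pairs approach -1.
#'
#' @param model a `parafac_model` with `n_components >= 1`.
#' @return list of F x F matrices `A`, `B`, `C`, `combined`; all symmetric
#'   with unit diagonal.
#' @export
component_congruence <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  cosmat <- function(m) {
    nrm <- sqrt(colSums(m^2))
    if (any(nrm == 0)) stop("zero-norm component column")
    crossprod(sweep(m, 2, nrm, "/"))
  }
  out <- lapply(list(A = model$A, B = model$B, C = model$C), cosmat)
  out$combined <- out$A * out$B * out$C
  out
}

#' Write a fitted PARAFAC model to a directory
#'
#' Three tab-separated loading tables (`A.tsv`, `B.tsv`, `C.tsv`, rows
#' labeled from the tensor's axis labels) plus `model.json` with F, fit,
#' convergence and seed metadata.
#'
#' @param model a `parafac_model`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_parafac <- function(model, path) {
  stopifnot(inherits(model, "parafac_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dump_loading <- function(m, file, axis) {
    df <- data.frame(label = if (is.null(rownames(m)))
      seq_len(nrow(m)) else rownames(m))
    colnames(m) <- paste0("comp", seq_len(ncol(m)))
    write.table(cbind(df, m), file.path(path, file), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  dump_loading(model$A, "A.tsv", "pair")
  dump_loading(model$B, "B.tsv", "stimulus")
  dump_loading(model$C, "C.tsv", "repetition")
  meta <- list(n_components = model$n_components,
               explained_variance = model$explained_variance,
               sse = model$sse, iterations = model$iterations,
               converged = model$converged, seed = model$seed,
               dims = model$dims)
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Plot PARAFAC loadings as three stacked panels
#'
#' One panel per mode (electrode pair, stimulus, repetition), all
#' components overlaid in color — the standard way loading profiles of a
#' trial-structured decomposition are read.
#'
#' @param x a `parafac_model`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.parafac_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panels <- list(`electrode pair` = x$A, stimulus = x$B, repetition = x$C)
  for (nm in names(panels)) {
    graphics::matplot(panels[[nm]], type = "l", lty = 1, xlab = nm,
                      ylab = "loading", main = nm, ...)
  }
  invisible(x)
}
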