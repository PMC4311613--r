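#' Mode-n matricization (unfolding) of a 3-way array
#'
#' `unfold(x, mode)` puts the chosen mode on the rows; columns run over
#' the two remaining modes in increasing mode order with the first of them
#' varying fastest (so mode-1 unfolding of an I x J x K array is I x JK
#' with the stimulus index fastest). `fold()` inverts it.
#'
#' @param x 3-way numeric array.
#' @param mode 1, 2 or 3.
#' @param m matrix produced by `unfold()`.
#' @param dims original array dimensions.
#' @param dn optional dimnames for the folded array.
#' @return `unfold()`: a matrix; `fold()`: a 3-way array.
#' @examples
#' x <- array(1:24, c(2, 3, 4))
#' all(fold(unfold(x, 2), 2, dim(x)) == x)  # TRUE
#' @export
unfold <- function(x, mode) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (!mode %in% 1:3) stop("'mode' must be 1, 2 or 3")
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(unclass(x), perm), nrow = dim(x)[mode])
}

#' @rdname unfold
#' @export
fold <- function(m, mode, dims, dn = NULL) {
  stopifnot(is.matrix(m), length(dims) == 3L)
  if (!mode %in% 1:3) stop("'mode' must be 1, 2 or 3")
  perm <- c(mode, setdiff(1:3, mode))
  out <- aperm(array(m, dims[perm]), order(perm))
  if (!is.null(dn)) dimnames(out) <- dn
  out
}

#' Principal component analysis of an unfolded tensor
#'
#' The bilinear baseline: column-centered singular value decomposition of
#' a matricized tensor, with variance shares from the squared singular
#' values. The default workflow unfolds along the repetition mode
#' (repetitions as observations), where a trilinear structure is spread
#' across many bilinear components and the contrast with PARAFAC is most
#' direct.
#'
#' @param m numeric matrix (observations x variables), at least 2 rows.
#' @param center column-center before decomposition (default `TRUE`).
#' @return object of class `pca_model`: `scores`, `loadings` (columns are
#'   components), `variance` (percent per component),
#'   `cumulative_variance` (percent), `center`, `mode` (set by
#'   [pca_on_tensor()], `NA` otherwise).
#' @export
pca_fit <- function(m, center = TRUE) {
  if (!is.matrix(m) || !all(is.finite(m))) stop("'m' must be a finite matrix")
  if (nrow(m) < 2L) stop("need at least 2 rows")
  total <- sum(scale(m, center = center, scale = FALSE)^2)
  if (total == 0) stop("matrix is constant: no variance to decompose")
  p <- prcomp(m, center = center, scale. = FALSE)
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation,
                 variance = var_pct,
                 cumulative_variance = cumsum(var_pct),
                 center = center, mode = NA_integer_),
            class = "pca_model")
}

#' @rdname pca_fit
#' @param x 3-way array (e.g. a `synchrony_tensor`).
#' @param mode unfolding mode used as observations, default 3
#'   (repetitions).
#' @export
pca_on_tensor <- function(x, mode = 3, center = TRUE) {
  out <- pca_fit(unfold(x, mode), center = center)
  out$mode <- as.integer(mode)
  out
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components, first explains %.2f%%%s\n",
              length(x$variance), x$variance[1],
              if (!is.na(x$mode)) sprintf(" (mode-%d unfolding)", x$mode)
              else ""))
  invisible(x)
}

#' Number of components needed to reach a cumulative-variance threshold
#'
#' Smallest `n` whose cumulative explained variance reaches the threshold.
#' If the threshold is numerically unreachable the model's rank is
#' returned with attribute `reached = FALSE`.
#'
#' @param model a `pca_model`.
#' @param threshold cumulative variance target in percent, in (0, 100].
#' @return integer count with attribute `reached`.
#' @export
components_needed <- function(model, threshold = 70) {
  stopifnot(inherits(model, "pca_model"))
  if (!(threshold > 0 && threshold <= 100))
    stop("'threshold' must be in (0, 100]")
  cv <- model$cumulative_variance
  hit <- which(cv >= threshold - 1e-9)
  if (!length(hit))
    return(structure(length(cv), reached = FALSE))
  structure(hit[1L], reached = TRUE)
}
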