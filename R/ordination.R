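#' Principal component analysis of transformed abundances
#'
#' Thin wrapper around [stats::prcomp()] returning scores, loadings and
#' per-component explained-variance fractions. For compositional data run
#' it on log-ratio coordinates ([ilr()] gives a full-rank orthonormal
#' representation); on log-ratio data columns share a scale, so the
#' default is centring without unit-variance scaling.
#'
#' @param X numeric matrix, samples x features.
#' @param ncomp number of components to keep; at most `min(n - 1, p)`.
#' @param center,scale passed to [stats::prcomp()].
#' @return An object of class `ordination`: list with `scores` (n x
#'   ncomp), `loadings` (p x ncomp), `explained` (fraction of total
#'   variance per kept component) and `eigenvalues` (all of them).
#' @export
pca_ord <- function(X, ncomp = 2, center = TRUE, scale = FALSE) {
  assert_matrix(X, "X")
  maxcomp <- min(nrow(X) - 1L, ncol(X))
  if (ncomp < 1 || ncomp > maxcomp)
    stop(sprintf("'ncomp' must be in [1, %d]", maxcomp), call. = FALSE)
  if (scale && any(apply(X, 2, stats::sd) == 0))
    stop("constant column(s); cannot scale to unit variance", call. = FALSE)
  fit <- stats::prcomp(X, center = center, scale. = scale)
  eig <- fit$sdev^2
  structure(list(scores = fit$x[, seq_len(ncomp), drop = FALSE],
                 loadings = fit$rotation[, seq_len(ncomp), drop = FALSE],
                 explained = (eig / sum(eig))[seq_len(ncomp)],
                 eigenvalues = eig,
                 method = "pca"),
            class = "ordination")
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(A, B) = 1 - 2 * sum_k min(A_k, B_k) / (sum A + sum B), the standard
#' abundance-based beta-diversity measure. Computed with
#' [vegan::vegdist()].
#'
#' @param x a [count_table()] or non-negative numeric matrix (samples x
#'   OTUs).
#' @return Symmetric numeric matrix with zero diagonal and the sample ids
#'   as dimnames.
#' @export
bray_curtis <- function(x) {
  m <- as_count_matrix(x)
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  if (any(rowSums(m) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "),
         call. = FALSE)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a sample dissimilarity matrix in Euclidean space by
#' eigendecomposition of the double-centred squared distances (via
#' [stats::cmdscale()]). For a non-Euclidean dissimilarity such as
#' Bray-Curtis some eigenvalues may be negative; they are dropped, their
#' count reported, and explained fractions computed over the positive
#' eigenvalues only.
#'
#' @param D symmetric dissimilarity matrix (or `dist`).
#' @param ncomp number of coordinates requested.
#' @return An `ordination` object with `scores`, `explained`,
#'   `eigenvalues` and `n_negative_eigenvalues`.
#' @export
pcoa_ord <- function(D, ncomp = 2) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  assert_matrix(D, "D")
  if (max(abs(D - t(D))) > 1e-12)
    stop("'D' must be symmetric", call. = FALSE)
  if (max(abs(diag(D))) > 1e-12)
    stop("'D' must have a zero diagonal", call. = FALSE)
  stopifnot(ncomp >= 1)
  n <- nrow(D)
  fit <- stats::cmdscale(stats::as.dist(D), k = min(ncomp, n - 1),
                         eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  if (!length(pos))
    stop("no positive eigenvalue; 'D' carries no Euclidean structure",
         call. = FALSE)
  n_neg <- sum(eig < -sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_neg > 0)
    message(sprintf("pcoa: dropped %d negative eigenvalue(s)", n_neg))
  k <- min(ncomp, ncol(fit$points))
  scores <- fit$points[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PCo", seq_len(k))
  structure(list(scores = scores,
                 explained = (pos / sum(pos))[seq_len(k)],
                 eigenvalues = eig,
                 n_negative_eigenvalues = n_neg,
                 method = "pcoa"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s: %d samples, %d components\n", toupper(x$method),
              nrow(x$scores), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
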