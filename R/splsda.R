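#' Multiclass sparse PLS discriminant analysis
#'
#' Fits a PLS2 model of the column-centred data matrix against the
#' centred dummy (one column per class) outcome, maximising the covariance
#' between linear combinations of the OTU coordinates and the class
#' membership. Sparsity is imposed componentwise by soft-thresholding the
#' X weight vector so that exactly `keepX[h]` OTUs carry a nonzero
#' loading on component h: the threshold is the (keepX[h]+1)-th largest
#' absolute weight, surviving entries are shrunk towards zero by it (lasso
#' shrinkage) and the vector is renormalized to unit norm. After each
#' component both X and Y are deflated by the regression of the component
#' score.
#'
#' For compositional counts, fit on CLR-transformed proportions (one
#' coordinate per OTU, so a selected coordinate is a selected OTU) or CSS
#' values; for repeated-measures designs pass the within-subject matrix
#' from [within_variation()].
#'
#' @param X numeric matrix, samples x features, with column names.
#' @param labels class label per row (factor or character); >= 2 classes.
#' @param ncomp number of components.
#' @param keepX integer vector (recycled to length `ncomp`) giving the
#'   number of features retained per component; defaults to all features,
#'   i.e. non-sparse PLS-DA.
#' @param tol,max_iter convergence tolerance and iteration cap of the
#'   weight/score updates per component. Convergence is linear with rate
#'   governed by the gap between the two leading singular values of
#'   `X'Y`, so near-degenerate problems may need over a thousand of these
#'   cheap (O(p K)) iterations; exhausting the cap raises an error naming
#'   the component.
#' @return An object of class `splsda`: list with `x_loadings` (p x H,
#'   unit-norm columns with exactly `keepX[h]` nonzeros), `x_scores`
#'   (n x H, mutually orthogonal), `y_loadings` (K x H regression
#'   coefficients of Y on the scores), `x_proj` (p x H deflation
#'   regressors), `x_means`, `y_means`, `keepX`, `classes`, `labels`.
#' @export
splsda <- function(X, labels, ncomp = 2, keepX = NULL,
                   tol = 1e-6, max_iter = 2000) {
  assert_matrix(X, "X")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  labels <- factor(labels)
  if (length(labels) != nrow(X))
    stop("'labels' must have one entry per row of 'X'", call. = FALSE)
  if (nlevels(labels) < 2)
    stop("need at least 2 classes", call. = FALSE)
  if (any(table(labels) < 1))
    stop("empty class level", call. = FALSE)
  n <- nrow(X); p <- ncol(X); K <- nlevels(labels)
  if (ncomp < 1 || ncomp > min(n - 1L, p))
    stop(sprintf("'ncomp' must be in [1, %d]", min(n - 1L, p)),
         call. = FALSE)
  if (is.null(keepX)) keepX <- p
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1 | keepX > p))
    stop(sprintf("'keepX' values must be in [1, %d]", p), call. = FALSE)

  Y <- dummy_matrix(labels)
  x_means <- colMeans(X)
  y_means <- colMeans(Y)
  Xh <- sweep(X, 2, x_means)
  Yh <- sweep(Y, 2, y_means)

  W <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  D <- matrix(0, K, ncomp, dimnames = list(levels(labels), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))

  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)                      # p x K
    sv <- svd(M, nu = 1, nv = 1)
    u <- drop(sv$u); v <- drop(sv$v)
    u <- normalize_vec(soft_keep(drop(M %*% v), keepX[h]))
    for (iter in seq_len(max_iter)) {
      u_old <- u
      v <- normalize_vec(drop(crossprod(M, u)))
      u <- normalize_vec(soft_keep(drop(M %*% v), keepX[h]))
      if (max(abs(u - u_old)) < tol) break
      if (iter == max_iter)
        stop(sprintf("sPLS-DA did not converge on component %d", h),
             call. = FALSE)
    }
    # deterministic sign: dominant loading positive
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    t_h <- drop(Xh %*% u)
    tt <- sum(t_h^2)
    if (tt < .Machine$double.eps)
      stop(sprintf("degenerate component %d (zero score variance)", h),
           call. = FALSE)
    p_h <- drop(crossprod(Xh, t_h)) / tt
    d_h <- drop(crossprod(Yh, t_h)) / tt
    W[, h] <- u; P[, h] <- p_h; D[, h] <- d_h; Tm[, h] <- t_h
    Xh <- Xh - tcrossprod(t_h, p_h)
    Yh <- Yh - tcrossprod(t_h, d_h)
  }
  colnames(W) <- colnames(P) <- colnames(D) <- colnames(Tm) <-
    paste0("comp", seq_len(ncomp))
  structure(list(x_loadings = W, x_scores = Tm, y_loadings = D,
                 x_proj = P, x_means = x_means, y_means = y_means,
                 keepX = keepX, ncomp = ncomp,
                 classes = levels(labels), labels = labels),
            class = "splsda")
}

# 0/1 indicator matrix, one column per class
dummy_matrix <- function(labels) {
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  Y
}

normalize_vec <- function(x) {
  nx <- vnorm(x)
  if (nx < .Machine$double.eps) stop("zero weight vector", call. = FALSE)
  x / nx
}

# lasso-style soft threshold keeping the `keep` largest |entries|:
# lambda = (keep+1)-th largest absolute value, survivors shrunk by it
soft_keep <- function(u, keep) {
  if (keep >= length(u)) return(u)
  lambda <- sort(abs(u), decreasing = TRUE)[keep + 1]
  sign(u) * pmax(abs(u) - lambda, 0)
}

#' Selected features of a sparse PLS-DA model
#'
#' @param model an `splsda` fit.
#' @param comp components to include (default all).
#' @return Character vector: union over the requested components of the
#'   feature ids with nonzero loading.
#' @export
selected_features <- function(model, comp = seq_len(model$ncomp)) {
  stopifnot(inherits(model, "splsda"))
  unique(unlist(lapply(comp, function(h)
    rownames(model$x_loadings)[model$x_loadings[, h] != 0])))
}

#' @export
print.splsda <- function(x, ...) {
  cat(sprintf("sPLS-DA: %d samples, %d features, %d classes, %d components\n",
              nrow(x$x_scores), nrow(x$x_loadings), length(x$classes),
              x$ncomp))
  cat("  keepX:", paste(x$keepX, collapse = ", "), "\n")
  invisible(x)
}

#' Predict classes from a sparse PLS-DA model
#'
#' New samples are centred with the training means and projected onto the
#' model scores; class is assigned per cumulative component count
#' 1..ncomp. `"max"` takes the argmax of the predicted dummy outcome;
#' `"centroid"` the nearest training class centroid in score space;
#' `"mahalanobis"` the nearest centroid under the pooled within-class
#' covariance of the training scores.
#'
#' @param object an `splsda` fit.
#' @param newdata numeric matrix whose columns match the training
#'   features.
#' @param distance prediction rule.
#' @param ... unused.
#' @return List with `class` (n x ncomp matrix of predicted labels, one
#'   column per cumulative component count), `scores` (projected
#'   coordinates) and `dummy` (predicted outcome values, n x K x ncomp).
#' @export
predict.splsda <- function(object, newdata,
                           distance = c("max", "centroid", "mahalanobis"),
                           ...) {
  distance <- match.arg(distance)
  assert_matrix(newdata, "newdata")
  if (ncol(newdata) != length(object$x_means) ||
      (!is.null(colnames(newdata)) &&
       !identical(colnames(newdata), names(object$x_means))))
    stop("'newdata' features do not match the training features",
         call. = FALSE)
  H <- object$ncomp
  K <- length(object$classes)
  Xc <- sweep(newdata, 2, object$x_means)
  # rotation absorbing the sequential deflation: T = Xc W (P'W)^{-1}
  R <- object$x_loadings %*% solve(crossprod(object$x_proj,
                                             object$x_loadings))
  scores <- Xc %*% R
  colnames(scores) <- colnames(object$x_scores)
  cls <- matrix(NA_character_, nrow(newdata), H,
                dimnames = list(rownames(newdata), colnames(scores)))
  dummy <- array(NA_real_, c(nrow(newdata), K, H),
                 dimnames = list(rownames(newdata), object$classes, NULL))
  for (h in seq_len(H)) {
    pred <- scores[, seq_len(h), drop = FALSE] %*%
      t(object$y_loadings[, seq_len(h), drop = FALSE])
    pred <- sweep(pred, 2, object$y_means, "+")
    dummy[, , h] <- pred
    cls[, h] <- switch(distance,
      max = object$classes[max.col(pred, ties.method = "first")],
      centroid = nearest_centroid(scores, object, h, pooled = FALSE),
      mahalanobis = nearest_centroid(scores, object, h, pooled = TRUE))
  }
  list(class = cls, scores = scores, dummy = dummy)
}

nearest_centroid <- function(scores, object, h, pooled = FALSE) {
  tr <- object$x_scores[, seq_len(h), drop = FALSE]
  ne <- scores[, seq_len(h), drop = FALSE]
  labs <- as.character(object$labels)
  cent <- rowsum(tr, labs)
  cent <- cent / as.vector(table(labs)[rownames(cent)])
  S <- if (pooled) {
    resid <- tr - cent[labs, , drop = FALSE]
    crossprod(resid) / (nrow(tr) - nrow(cent))
  } else diag(h)
  Sinv <- solve(S)
  d2 <- vapply(seq_len(nrow(cent)), function(k) {
    delta <- sweep(ne, 2, cent[k, ])
    rowSums((delta %*% Sinv) * delta)
  }, numeric(nrow(ne)))
  if (!is.matrix(d2)) d2 <- matrix(d2, nrow = nrow(ne))
  rownames(cent)[max.col(-d2, ties.method = "first")]
}
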