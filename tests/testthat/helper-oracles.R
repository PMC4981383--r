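# Independent oracles used by the tests. These deliberately take a
# different computational route from the package code.

# classical NIPALS PLS2 with the inner y-score exchange loop
nipals_pls2 <- function(X, Y, ncomp, tol = 1e-12, max_iter = 5000) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  W <- P <- matrix(0, ncol(X), ncomp)
  D <- matrix(0, ncol(Y), ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u)); w <- w / sqrt(sum(w^2))
      t <- drop(Xc %*% w)
      q <- drop(crossprod(Yc, t)); q <- q / sqrt(sum(q^2))
      u_new <- drop(Yc %*% q)
      if (max(abs(u_new - u)) < tol) { u <- u_new; break }
      u <- u_new
    }
    t <- drop(Xc %*% w); tt <- sum(t^2)
    pv <- drop(crossprod(Xc, t)) / tt
    d <- drop(crossprod(Yc, t)) / tt
    W[, h] <- w; P[, h] <- pv; D[, h] <- d; Tm[, h] <- t
    Xc <- Xc - tcrossprod(t, pv)
    Yc <- Yc - tcrossprod(t, d)
  }
  list(W = W, scores = Tm, P = P, D = D)
}

dummy_oracle <- function(labels) {
  labels <- factor(labels)
  Y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

# random count table with ids
random_count_table <- function(n = 6, p = 8, lambda = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n * p, lambda), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("OTU%03d", seq_len(p))))
  count_table(m)
}

# strictly positive random compositions (rows sum to 1)
random_compositions <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rgamma(n * p, shape = 1), n, p)
  sweep(g, 1, rowSums(g), "/")
}

# align score matrix column signs to a reference before comparison
align_signs <- function(A, ref) {
  for (j in seq_len(ncol(A)))
    if (sum(A[, j] * ref[, j]) < 0) A[, j] <- -A[, j]
  A
}
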