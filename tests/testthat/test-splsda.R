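toy_classes <- function(n_per = 10, p = 20, shift = 3, seed = 1,
                        classes = c("a", "b", "c")) {
  set.seed(seed)
  n <- n_per * length(classes)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("f", seq_len(p))))
  y <- rep(classes, each = n_per)
  for (k in seq_along(classes))   # class k shifted on feature k
    X[y == classes[k], k] <- X[y == classes[k], k] + shift
  list(X = X, y = y)
}

test_that("keepX = p reproduces a dense NIPALS PLS2 oracle", {
  d <- toy_classes(n_per = 10, p = 20, seed = 4)
  fit <- splsda(d$X, d$y, ncomp = 3, keepX = 20, tol = 1e-12)
  oracle <- nipals_pls2(d$X, dummy_oracle(d$y), ncomp = 3)
  rel <- max(abs(align_signs(fit$x_scores, oracle$scores) -
                   oracle$scores)) / max(abs(oracle$scores))
  expect_lt(rel, 1e-8)
  relw <- max(abs(align_signs(fit$x_loadings, oracle$W) - oracle$W))
  expect_lt(relw, 1e-8)
})

test_that("selection is exact: nnz per component equals keepX", {
  d <- toy_classes(seed = 7)
  for (kx in list(c(1, 1), c(5, 17), c(20, 3))) {
    fit <- splsda(d$X, d$y, ncomp = 2, keepX = kx)
    expect_equal(unname(colSums(fit$x_loadings != 0)), kx)
    expect_equal(unname(sqrt(colSums(fit$x_loadings^2))), c(1, 1),
                 tolerance = 1e-10)
  }
  expect_error(splsda(d$X, d$y, keepX = 0), "keepX")
  expect_error(splsda(d$X, d$y, keepX = 21), "keepX")
})

test_that("soft thresholding shrinks survivors by the cut value and renormalizes", {
  # (0.9, -0.5, 0.1), keepX = 2: lambda = 0.1 -> (0.8, -0.4, 0) / norm
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("f", 1:3)))
  # construct a response whose covariance vector with X is (0.9, -0.5, 0.1)
  target <- c(0.9, -0.5, 0.1)
  u <- micropls:::soft_keep(target, 2)
  expect_equal(u, c(0.8, -0.4, 0))
  expect_equal(micropls:::normalize_vec(u),
               c(0.89442719, -0.44721360, 0), tolerance = 1e-8)
})

test_that("a single discriminative feature is found with keepX = 1", {
  set.seed(10)
  X <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("a", "b"), each = 20)
  X[y == "b", 1] <- X[y == "b", 1] + 5   # only feature 1 separates
  fit <- splsda(X, y, ncomp = 1, keepX = 1)
  expect_equal(selected_features(fit), "f1")
  # oracle: rank-1 SVD of X'Y has its dominant weight on feature 1
  Xc <- scale(X, scale = FALSE); Yc <- scale(dummy_oracle(y), scale = FALSE)
  u1 <- svd(crossprod(Xc, Yc))$u[, 1]
  expect_equal(which.max(abs(u1)), 1L)
})

test_that("scores are mutually orthogonal", {
  d <- toy_classes(n_per = 12, p = 30, seed = 5)
  fit <- splsda(d$X, d$y, ncomp = 4, keepX = c(30, 10, 5, 30))
  G <- crossprod(fit$x_scores)
  offdiag <- abs(G[upper.tri(G)]) / max(diag(G))
  expect_lt(max(offdiag), 1e-8)
})

test_that("prediction rules behave on separable, degenerate and random data", {
  d <- toy_classes(shift = 6, seed = 6)
  fit <- splsda(d$X, d$y, ncomp = 2, keepX = c(10, 10))
  expect_equal(unname(predict(fit, d$X)$class[, 2]), d$y)  # 0 training errors

  # identical new rows get one constant prediction
  one <- d$X[rep(1, 4), , drop = FALSE]
  rownames(one) <- paste0("r", 1:4)
  expect_equal(length(unique(predict(fit, one)$class[, 2])), 1L)

  # centroid rule agrees with brute-force nearest centroid in score space
  set.seed(20)
  Xnew <- matrix(rnorm(15 * 20), 15, 20,
                 dimnames = list(NULL, colnames(d$X)))
  pr <- predict(fit, Xnew, distance = "centroid")
  cent <- rowsum(fit$x_scores, d$y) / as.vector(table(d$y))
  brute <- apply(pr$scores, 1, function(s)
    rownames(cent)[which.min(colSums((t(cent) - s)^2))])
  expect_equal(unname(pr$class[, 2]), unname(brute))

  expect_error(predict(fit, Xnew[, 1:5]), "features")
})

test_that("training error is non-increasing in components on separable data", {
  d <- toy_classes(shift = 4, seed = 12)
  fit <- splsda(d$X, d$y, ncomp = 4, keepX = 10)
  errs <- vapply(1:4, function(h)
    mean(predict(fit, d$X)$class[, h] != d$y), numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("fit agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  d <- toy_classes(n_per = 10, p = 20, seed = 2)
  y <- factor(d$y)
  mine_dense <- splsda(d$X, y, ncomp = 2, tol = 1e-10)
  ref_dense <- mixOmics::splsda(d$X, y, ncomp = 2, scale = FALSE)
  for (h in 1:2)
    expect_equal(abs(cor(mine_dense$x_scores[, h],
                         ref_dense$variates$X[, h])), 1,
                 tolerance = 1e-6)
  mine_sparse <- splsda(d$X, y, ncomp = 2, keepX = c(5, 7), tol = 1e-10)
  ref_sparse <- mixOmics::splsda(d$X, y, ncomp = 2, scale = FALSE,
                                 keepX = c(5, 7))
  for (h in 1:2) {
    sel_mine <- rownames(mine_sparse$x_loadings)[
      mine_sparse$x_loadings[, h] != 0]
    sel_ref <- mixOmics::selectVar(ref_sparse, comp = h)$name
    expect_setequal(sel_mine, sel_ref)
  }
})
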