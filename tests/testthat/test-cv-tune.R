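separable_data <- function(n_per = 15, p = 12, shift = 6, seed = 1) {
  set.seed(seed)
  classes <- c("a", "b", "c")
  n <- n_per * 3
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("f", seq_len(p))))
  y <- rep(classes, each = n_per)
  for (k in 1:3) X[y == classes[k], k] <- X[y == classes[k], k] + shift
  list(X = X, y = y)
}

test_that("cross-validation is near-perfect on separable data", {
  d <- separable_data()
  cv <- perf_splsda(d$X, d$y, ncomp = 2, keepX = 6, folds = 5,
                    repeats = 3, seed = 3)
  expect_lt(cv$error[2], 0.02)
  expect_true(all(cv$error >= 0 & cv$error <= 1))
  expect_true(all(cv$ber >= 0 & cv$ber <= 1))
  expect_true(all(cv$error_sd >= 0))
  expect_equal(dim(cv$per_class), c(3L, 2L))
})

test_that("a fixed seed reproduces the identical CV result", {
  d <- separable_data(shift = 0.8, seed = 5)  # hard problem: nonzero error
  cv1 <- perf_splsda(d$X, d$y, ncomp = 2, keepX = 4, folds = 4,
                     repeats = 2, seed = 11)
  cv2 <- perf_splsda(d$X, d$y, ncomp = 2, keepX = 4, folds = 4,
                     repeats = 2, seed = 11)
  expect_identical(cv1, cv2)
  cv3 <- perf_splsda(d$X, d$y, ncomp = 2, keepX = 4, folds = 4,
                     repeats = 2, seed = 12)
  expect_false(identical(cv1$error, cv3$error))
})

test_that("subject-level folds keep all rows of a subject together", {
  set.seed(8)
  subjects <- rep(sprintf("subj%d", 1:12), each = 3)
  labels <- factor(rep(c("a", "b", "c"), 12))
  fold <- micropls:::make_folds(labels, 4, subjects)
  expect_true(all(tapply(fold, subjects,
                         function(f) length(unique(f))) == 1))
  # stratified row-level folds balance classes across folds
  fold2 <- micropls:::make_folds(labels, 3)
  expect_true(all(table(fold2, labels) == 4))
})

test_that("permuted labels give chance-level error on two balanced classes", {
  set.seed(17)
  X <- matrix(rnorm(80 * 20), 80, 20,
              dimnames = list(paste0("s", 1:80), paste0("f", 1:20)))
  y <- sample(rep(c("a", "b"), each = 40))
  cv <- perf_splsda(X, y, ncomp = 1, keepX = 20, folds = 10,
                    repeats = 5, seed = 19)
  expect_gt(cv$error[1], 0.38)
  expect_lt(cv$error[1], 0.62)
})

test_that("tuning selects a parsimonious grid minimum and refits on all data", {
  d <- separable_data(seed = 23)
  tn <- tune_splsda(d$X, d$y, keepX_grid = c(2, 4, 8, 12), max_comp = 3,
                    folds = 4, repeats = 2, seed = 29)
  expect_true(all(tn$choice_keepX %in% c(2, 4, 8, 12)))
  # chosen keepX attains the row minimum of the error surface
  for (h in seq_len(tn$ncomp)) {
    expect_equal(tn$error[h], min(tn$error_surface[h, ]))
    expect_equal(tn$choice_keepX[h],
                 as.integer(colnames(tn$error_surface)[
                   which.min(tn$error_surface[h, ])]))
  }
  expect_s3_class(tn$final, "splsda")
  expect_equal(tn$final$keepX, tn$choice_keepX)
  expect_equal(tn$final$ncomp, tn$ncomp)

  # grid = {p} reduces to dense PLS-DA
  tn_dense <- tune_splsda(d$X, d$y, keepX_grid = ncol(d$X), max_comp = 2,
                          folds = 4, repeats = 2, seed = 29)
  expect_true(all(tn_dense$choice_keepX == ncol(d$X)))
  expect_error(tune_splsda(d$X, d$y, keepX_grid = c(5, 999)), "keepX_grid")

  # reproducibility of the surface under a fixed seed
  tn2 <- tune_splsda(d$X, d$y, keepX_grid = c(2, 4, 8, 12), max_comp = 3,
                     folds = 4, repeats = 2, seed = 29)
  expect_identical(tn$error_surface, tn2$error_surface)
})

test_that("multilevel CV outperforms plain CV under strong subject effects", {
  sim <- simulate_counts(synth_config(n_subjects = 20, n_otus = 100,
                                      n_discriminative = 6, effect_size = 4,
                                      subject_effect_sd = 2.5, seed = 37))
  X <- clr(tss(add_pseudocount(sim$table)))
  md <- sim$metadata
  ml <- perf_splsda(X, md$class_label, ncomp = 2, keepX = 18, folds = 4,
                    repeats = 3, seed = 41, subjects = md$subject_id,
                    multilevel = TRUE)
  plain <- perf_splsda(X, md$class_label, ncomp = 2, keepX = 18, folds = 4,
                       repeats = 3, seed = 41, subjects = md$subject_id,
                       multilevel = FALSE)
  expect_lt(ml$error[2], plain$error[2])
  # legacy row-level folding on the precomputed within matrix also runs
  legacy <- perf_splsda(X, md$class_label, ncomp = 1, keepX = 18, folds = 4,
                        repeats = 2, seed = 41, subjects = md$subject_id,
                        multilevel = TRUE, legacy_cv = TRUE)
  expect_true(is.finite(legacy$error[1]))
})
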