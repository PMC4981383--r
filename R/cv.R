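#' Cross-validated performance of sparse PLS-DA
#'
#' Estimates the classification error rate of [splsda()] by repeated
#' stratified k-fold cross-validation. Within each repeat every sample is
#' predicted exactly once; the overall error (fraction misclassified) and
#' the balanced error rate (mean of per-class error rates) are recorded
#' for every cumulative component count 1..ncomp, then averaged over
#' repeats. Fold draws use `seed + r` for repeat r, so results are fully
#' reproducible.
#'
#' When `subjects` is given, all rows of a subject are assigned to the
#' same fold, preventing leakage between repeated measures of one
#' individual. With `multilevel = TRUE` the within-subject decomposition
#' is recomputed on each training split (and the test split is decomposed
#' with its own subject means), so no subject-mean information crosses the
#' split; `legacy_cv = TRUE` instead decomposes the full matrix once and
#' folds at the row level.
#'
#' @param X numeric matrix, samples x features (transformed counts; the
#'   raw transformed matrix, not the within-matrix, when
#'   `multilevel = TRUE`).
#' @param labels class label per row.
#' @param ncomp maximum number of components to evaluate.
#' @param keepX features kept per component (recycled); default all.
#' @param folds number of cross-validation folds (>= 2).
#' @param repeats number of repetitions with fresh fold draws.
#' @param seed integer seed; repeat r draws folds with `seed + r`.
#' @param subjects optional subject id per row; forces subject-level
#'   folds.
#' @param multilevel recompute the within-subject decomposition inside
#'   each split (requires `subjects`).
#' @param legacy_cv with `multilevel`: decompose once up front and fold at
#'   the row level instead.
#' @param distance prediction rule, see [predict.splsda()].
#' @return An object of class `splsda_cv`: list with `error`, `error_sd`,
#'   `ber`, `ber_sd` (each a vector over component counts), `per_class`
#'   (class x component matrix of mean per-class error), and the CV
#'   settings.
#' @export
perf_splsda <- function(X, labels, ncomp = 2, keepX = NULL, folds = 10,
                        repeats = 10, seed = 1, subjects = NULL,
                        multilevel = FALSE, legacy_cv = FALSE,
                        distance = "max") {
  assert_matrix(X, "X")
  labels <- factor(labels)
  stopifnot(folds >= 2, repeats >= 1)
  if (multilevel && is.null(subjects))
    stop("'multilevel' requires 'subjects'", call. = FALSE)
  if (!is.null(subjects)) subjects <- as.character(subjects)
  if (multilevel && legacy_cv) {
    X <- within_variation(X, subjects)$within
    fold_subjects <- NULL          # row-level folds on the within matrix
    multilevel <- FALSE
  } else {
    fold_subjects <- subjects
  }
  K <- nlevels(labels)
  err <- ber <- matrix(NA_real_, repeats, ncomp)
  per_class <- array(NA_real_, c(K, ncomp, repeats),
                     dimnames = list(levels(labels), NULL, NULL))
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold <- draw_valid_folds(labels, folds, fold_subjects)
    pred <- matrix(NA_character_, length(labels), ncomp)
    for (f in sort(unique(fold))) {
      test <- fold == f
      Xtr <- X[!test, , drop = FALSE]
      Xte <- X[test, , drop = FALSE]
      if (multilevel) {
        Xtr <- within_variation(Xtr, subjects[!test])$within
        Xte <- suppressWarnings(
          within_variation(Xte, subjects[test],
                           allow_singletons = TRUE)$within)
      }
      fit <- splsda(Xtr, labels[!test], ncomp = ncomp, keepX = keepX)
      pred[test, ] <- predict(fit, Xte, distance = distance)$class
    }
    for (h in seq_len(ncomp)) {
      wrong <- pred[, h] != as.character(labels)
      err[r, h] <- mean(wrong)
      cls_err <- tapply(wrong, labels, mean)
      per_class[, h, r] <- cls_err[levels(labels)]
      ber[r, h] <- mean(cls_err)
    }
  }
  structure(list(error = colMeans(err), error_sd = apply(err, 2, stats::sd),
                 ber = colMeans(ber), ber_sd = apply(ber, 2, stats::sd),
                 per_class = apply(per_class, c(1, 2), mean),
                 folds = folds, repeats = repeats, seed = seed,
                 distance = distance, keepX = keepX, ncomp = ncomp),
            class = "splsda_cv")
}

#' @export
print.splsda_cv <- function(x, ...) {
  cat(sprintf("sPLS-DA cross-validation: %d-fold x %d repeats (seed %d)\n",
              x$folds, x$repeats, x$seed))
  for (h in seq_along(x$error))
    cat(sprintf("  comp %d: error %.3f (sd %.3f), BER %.3f\n",
                h, x$error[h], x$error_sd[h], x$ber[h]))
  invisible(x)
}

# stratified folds; with subjects, whole subjects are assigned to folds.
# redrawn (up to 10 times) if some training split loses an entire class.
draw_valid_folds <- function(labels, nfolds, subjects = NULL) {
  for (attempt in seq_len(10)) {
    fold <- make_folds(labels, nfolds, subjects)
    ok <- all(vapply(unique(fold), function(f)
      nlevels(droplevels(labels[fold != f])) == nlevels(labels),
      logical(1)))
    if (ok) return(fold)
    warning("a training split lost an entire class; redrawing folds",
            call. = FALSE)
  }
  stop("could not draw folds keeping every class in every training split",
       call. = FALSE)
}

make_folds <- function(labels, nfolds, subjects = NULL) {
  if (is.null(subjects)) {
    fold <- integer(length(labels))
    for (k in levels(labels)) {
      idx <- which(labels == k)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(nfolds), length(idx))
    }
  } else {
    us <- unique(subjects)
    us <- us[sample.int(length(us))]
    f <- rep_len(sample.int(nfolds), length(us))
    fold <- f[match(subjects, us)]
  }
  fold
}

#' Tune the number of features and components of sparse PLS-DA
#'
#' Sequential componentwise search: with the keepX of earlier components
#' fixed at their chosen values, the grid is evaluated by cross-validation
#' for the current component and the value with the lowest mean error is
#' chosen (ties broken towards the smaller, more parsimonious keepX). A
#' further component is added only while it lowers the mean error by more
#' than one standard deviation of the candidate error; the final model is
#' then refit on the entire data set with the chosen settings.
#'
#' The same seed is passed to every [perf_splsda()] call, so all grid
#' values of a component are compared on identical fold draws.
#'
#' @inheritParams perf_splsda
#' @param keepX_grid integer grid of candidate keepX values; the default
#'   spans 5..50 by 5 and 60..200 by 20, capped at p.
#' @param max_comp maximum number of components to consider.
#' @param measure error to minimise: overall error rate or balanced error
#'   rate.
#' @return An object of class `splsda_tune`: list with `choice_keepX`,
#'   `ncomp`, `error` (chosen mean error per kept component),
#'   `error_surface` and `error_sd_surface` (component x grid), and
#'   `final`, the model refit on all data (on the within-matrix when
#'   `multilevel = TRUE`).
#' @export
tune_splsda <- function(X, labels, keepX_grid = default_keepx_grid(ncol(X)),
                        max_comp = 3, folds = 10, repeats = 10, seed = 1,
                        subjects = NULL, multilevel = FALSE,
                        legacy_cv = FALSE, distance = "max",
                        measure = c("overall", "ber")) {
  assert_matrix(X, "X")
  measure <- match.arg(measure)
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  if (any(keepX_grid < 1 | keepX_grid > ncol(X)))
    stop(sprintf("'keepX_grid' values must be in [1, %d]", ncol(X)),
         call. = FALSE)
  surface <- sd_surface <- matrix(
    NA_real_, max_comp, length(keepX_grid),
    dimnames = list(paste0("comp", seq_len(max_comp)), keepX_grid))
  chosen <- integer(0)
  best_err <- best_sd <- numeric(0)
  for (h in seq_len(max_comp)) {
    for (j in seq_along(keepX_grid)) {
      cv <- perf_splsda(X, labels, ncomp = h,
                        keepX = c(chosen, keepX_grid[j]), folds = folds,
                        repeats = repeats, seed = seed, subjects = subjects,
                        multilevel = multilevel, legacy_cv = legacy_cv,
                        distance = distance)
      surface[h, j] <- if (measure == "overall") cv$error[h] else cv$ber[h]
      sd_surface[h, j] <- if (measure == "overall") cv$error_sd[h] else
        cv$ber_sd[h]
    }
    j_best <- which.min(surface[h, ])   # ties -> smallest keepX
    if (h > 1 &&
        !(surface[h, j_best] < best_err[h - 1] - sd_surface[h, j_best]))
      break
    chosen <- c(chosen, keepX_grid[j_best])
    best_err <- c(best_err, surface[h, j_best])
    best_sd <- c(best_sd, sd_surface[h, j_best])
  }
  Xfit <- if (multilevel) within_variation(X, subjects)$within else X
  final <- splsda(Xfit, labels, ncomp = length(chosen), keepX = chosen)
  structure(list(choice_keepX = chosen, ncomp = length(chosen),
                 error = best_err, error_sd = best_sd,
                 error_surface = surface[seq_len(min(
                   length(chosen) + 1, max_comp)), , drop = FALSE],
                 error_sd_surface = sd_surface[seq_len(min(
                   length(chosen) + 1, max_comp)), , drop = FALSE],
                 keepX_grid = keepX_grid, measure = measure,
                 folds = folds, repeats = repeats, seed = seed,
                 final = final),
            class = "splsda_tune")
}

#' @rdname tune_splsda
#' @param p number of features.
#' @export
default_keepx_grid <- function(p) {
  sort(unique(pmin(c(seq(5, 50, by = 5), seq(60, 200, by = 20)), p)))
}

#' @export
print.splsda_tune <- function(x, ...) {
  cat(sprintf("sPLS-DA tuning (%s error, %d-fold x %d repeats)\n",
              x$measure, x$folds, x$repeats))
  cat(sprintf("  chosen: %d component(s), keepX = %s\n", x$ncomp,
              paste(x$choice_keepX, collapse = ", ")))
  cat("  error per component:",
      paste(sprintf("%.3f", x$error), collapse = ", "), "\n")
  invisible(x)
}
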