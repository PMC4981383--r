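#' Within-subject variance decomposition
#'
#' Splits a repeated-measures data matrix into between-subject variation
#' (each row replaced by its subject's mean) and within-subject variation
#' (the deviation of each observation from its subject mean). In designs
#' where the same subjects are sampled in several habitats or body sites,
#' the between part carries the — often dominant — individual variation;
#' the within part isolates the habitat differences and is the input for
#' the downstream ordination or discriminant analysis. Apply it to
#' log-ratio or CSS transformed data, not raw counts.
#'
#' The grand mean is not added back to the within matrix; downstream PCA
#' and PLS centre columns anyway, so scores are unaffected.
#'
#' @param X numeric matrix (samples x features), already transformed.
#' @param subjects subject identifier per row of `X`.
#' @param allow_singletons if `TRUE`, a subject with a single observation
#'   gets a zero within-row (with a warning) instead of raising an error.
#' @return An object of class `multilevel_decomposition`: list with
#'   `within` and `between` matrices (same shape as `X`, `within +
#'   between == X`), and `subjects`.
#' @export
within_variation <- function(X, subjects, allow_singletons = FALSE) {
  assert_matrix(X, "X")
  subjects <- as.character(subjects)
  if (length(subjects) != nrow(X))
    stop("'subjects' must have one entry per row of 'X'", call. = FALSE)
  counts <- table(subjects)
  single <- names(counts)[counts < 2]
  if (length(single)) {
    if (!allow_singletons)
      stop("subject(s) with a single observation: ",
           paste(single, collapse = ", "),
           " (set allow_singletons = TRUE to keep them with zero ",
           "within-variation)", call. = FALSE)
    warning("subject(s) with a single observation get zero within-rows: ",
            paste(single, collapse = ", "), call. = FALSE)
  }
  means <- rowsum(X, subjects)
  means <- means / as.vector(counts[rownames(means)])
  between <- means[subjects, , drop = FALSE]
  dimnames(between) <- dimnames(X)
  structure(list(within = X - between, between = between,
                 subjects = subjects),
            class = "multilevel_decomposition")
}

#' @export
print.multilevel_decomposition <- function(x, ...) {
  cat(sprintf(
    "multilevel decomposition: %d observations, %d subjects, %d features\n",
    nrow(x$within), length(unique(x$subjects)), ncol(x$within)))
  ssw <- sum(x$within^2)
  ssb <- sum(scale(x$between, scale = FALSE)^2)
  cat(sprintf("  SS within: %.4g; SS between (centred): %.4g\n", ssw, ssb))
  invisible(x)
}
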