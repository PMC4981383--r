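#' Total sum scaling
#'
#' Converts counts to proportions by dividing each sample's counts by its
#' library total, removing differences in sequencing depth. The output
#' lives on the simplex: only relative abundances are meaningful, and
#' log-ratio transforms ([clr()], [ilr()]) should be applied before
#' Euclidean methods. Use [add_pseudocount()] first if the downstream
#' transform requires strictly positive entries.
#'
#' @param x a [count_table()] or numeric matrix (samples x OTUs).
#' @return Numeric matrix of proportions; every row sums to 1.
#' @export
tss <- function(x) {
  m <- as_count_matrix(x)
  totals <- rowSums(m)
  if (any(totals <= 0))
    stop("zero total count for sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  sweep(m, 1, totals, "/")
}

#' Centred log-ratio transform
#'
#' Maps each composition x = (x_1, ..., x_p) to
#' y_j = log(x_j / g(x)) with g(x) the geometric mean of the row,
#' projecting the simplex onto the zero-sum hyperplane of R^p. Keeps one
#' coordinate per OTU, which is what componentwise feature selection
#' needs.
#'
#' @param x numeric matrix of strictly positive values (samples x OTUs);
#'   rows are treated as compositions (any positive rescaling of a row
#'   gives the same output).
#' @return Numeric matrix, same dimensions as `x`; rows sum to 0.
#' @export
clr <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else x
  assert_matrix(m, "x")
  if (any(m <= 0))
    stop("clr requires strictly positive entries; add a pseudocount first",
         call. = FALSE)
  lm_ <- log(m)
  lm_ - rowMeans(lm_)
}

#' Isometric log-ratio transform (pivot coordinates)
#'
#' Expresses each p-part composition in p-1 orthonormal log-ratio
#' coordinates, preserving Aitchison geometry: Euclidean distances between
#' ILR rows equal Aitchison distances between compositions. The basis is
#' the pivot (sequential binary partition) convention,
#' y_i = sqrt(i/(i+1)) * log(g(x_1..x_i) / x_{i+1}), i = 1..p-1.
#'
#' @param x numeric matrix of strictly positive values (samples x OTUs),
#'   p >= 2 columns.
#' @return Numeric matrix with p-1 columns named `ilr1` ... `ilr(p-1)`.
#' @export
ilr <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else x
  assert_matrix(m, "x")
  p <- ncol(m)
  if (p < 2) stop("ilr requires at least 2 parts", call. = FALSE)
  if (any(m <= 0))
    stop("ilr requires strictly positive entries; add a pseudocount first",
         call. = FALSE)
  out <- clr(m) %*% t(ilr_basis(p))
  colnames(out) <- paste0("ilr", seq_len(p - 1))
  rownames(out) <- rownames(m)
  out
}

#' Orthonormal contrast matrix of the pivot ILR basis
#'
#' Returns the (p-1) x p matrix V with orthonormal, zero-sum rows such
#' that `ilr(x) == clr(x) %*% t(V)`.
#'
#' @param p number of parts.
#' @return A (p-1) x p numeric matrix.
#' @export
ilr_basis <- function(p) {
  stopifnot(p >= 2)
  V <- matrix(0, p - 1, p)
  for (i in seq_len(p - 1)) {
    V[i, seq_len(i)] <- sqrt(1 / (i * (i + 1)))
    V[i, i + 1] <- -sqrt(i / (i + 1))
  }
  V
}

#' Cumulative sum scaling normalization
#'
#' Scales each sample by the sum of its counts up to a quantile chosen so
#' that, across samples, the scaled segment of the count distribution is
#' relatively invariant — a robust alternative to total sum scaling when
#' libraries differ in how deeply they sample the community. Sample j's
#' scaling factor is s_j = sum of counts in j that are <= the chosen
#' quantile of j's positive counts; normalized values are
#' count / (s_j / 1000), optionally followed by log(x + 1).
#'
#' The `"auto"` percentile starts from the median and picks the smallest
#' quantile level at which the median absolute deviation of sample
#' quantiles around their across-sample mean starts changing sharply
#' (relative change > 0.1); it falls back to 0.5 when the search is
#' unstable (e.g. too few samples or degenerate quantiles).
#'
#' @param x a [count_table()] or numeric matrix of counts.
#' @param percentile `"auto"` or a fixed quantile level in (0, 1).
#' @param log_base base of the final log(x + 1) transform: 2 (default),
#'   `exp(1)`, or `NULL` to skip the log step.
#' @param scaling_constant divisor applied to scaling factors (default
#'   1000), so normalized values are counts per `scaling_constant`
#'   reference counts.
#' @return Numeric matrix of normalized (optionally logged) values, with
#'   attributes `percentile` (level used) and `scaling_factors`.
#' @export
css <- function(x, percentile = "auto", log_base = 2,
                scaling_constant = 1000) {
  m <- as_count_matrix(x)
  if (nrow(m) < 2) stop("css requires at least 2 samples", call. = FALSE)
  if (identical(percentile, "auto")) {
    percentile <- css_auto_percentile(m)
  } else {
    stopifnot(is.numeric(percentile), percentile > 0, percentile < 1)
  }
  s <- apply(m, 1, function(row) {
    pos <- row[row > 0]
    if (!length(pos)) return(0)
    q <- stats::quantile(pos, probs = percentile, names = FALSE)
    sum(row[row <= q])
  })
  if (any(s == 0))
    stop("zero CSS scaling factor for sample(s): ",
         paste(rownames(m)[s == 0], collapse = ", "), call. = FALSE)
  out <- m / (s / scaling_constant)
  if (!is.null(log_base)) out <- log(out + 1, base = log_base)
  attr(out, "percentile") <- percentile
  attr(out, "scaling_factors") <- s
  out
}

# data-driven percentile search: per-sample quantile curves of positive
# counts; instability measured as relative change in the median absolute
# deviation of the sample quantiles around their across-sample mean
css_auto_percentile <- function(m, levels = seq(0.5, 0.99, by = 0.01),
                                threshold = 0.1) {
  qs <- vapply(levels, function(l) {
    apply(m, 1, function(row) {
      pos <- row[row > 0]
      if (!length(pos)) return(NA_real_)
      stats::quantile(pos, probs = l, names = FALSE)
    })
  }, numeric(nrow(m)))
  if (any(is.na(qs))) return(0.5)
  dev <- apply(qs, 2, function(col) stats::median(abs(col - mean(col))))
  if (all(dev == 0)) return(0.5)
  rel <- abs(diff(dev)) / ifelse(dev[-length(dev)] > 0,
                                 dev[-length(dev)], Inf)
  hit <- which(rel > threshold)
  if (!length(hit)) return(0.5)
  levels[hit[1]]
}
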