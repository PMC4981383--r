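#' Remove samples with very low sequencing depth
#'
#' Drops samples whose total OTU count is below `min_total` (default 10,
#' the conventional threshold for discarding failed libraries). Survivors
#' keep their order and values.
#'
#' @param x a [count_table()].
#' @param min_total minimum total count a sample must reach to be kept.
#' @return The filtered `count_table`.
#' @export
filter_samples <- function(x, min_total = 10) {
  stopifnot(inherits(x, "count_table"), min_total >= 0)
  keep <- rowSums(x$counts) >= min_total
  if (!any(keep)) stop("empty table after sample filter", call. = FALSE)
  if (!all(keep))
    message(sprintf("filter_samples: removed %d sample(s) with total < %g",
                    sum(!keep), min_total))
  count_table(x$counts[keep, , drop = FALSE], taxonomy = x$taxonomy)
}

#' Remove rare OTUs by overall proportional abundance
#'
#' An OTU is kept iff its aggregate count across all samples, divided by
#' the grand total of the table, is at least `min_prop`. The default
#' 1e-4 (0.01%) counteracts sequencing error: spurious OTUs at the
#' ~1/1000 Illumina error rate fall below it. Removal is strict-below, so
#' an OTU at exactly `min_prop` is kept. Apply after [filter_samples()]
#' so the denominator reflects the retained samples.
#'
#' @param x a [count_table()].
#' @param min_prop minimum aggregate proportion, in `[0, 1)`.
#' @return The filtered `count_table`.
#' @export
filter_otus <- function(x, min_prop = 1e-4) {
  stopifnot(inherits(x, "count_table"), min_prop >= 0, min_prop < 1)
  total <- sum(x$counts)
  if (total == 0) stop("table has no counts", call. = FALSE)
  keep <- colSums(x$counts) / total >= min_prop
  if (!any(keep)) stop("empty table after OTU filter", call. = FALSE)
  if (!all(keep))
    message(sprintf(
      "filter_otus: removed %d OTU(s) below %.4g%% of total counts",
      sum(!keep), 100 * min_prop))
  count_table(x$counts[, keep, drop = FALSE], taxonomy = x$taxonomy)
}

#' Add a pseudocount before log-ratio transformation
#'
#' Log ratios are undefined on zero counts, so on the log-ratio branch
#' (TSS followed by CLR or ILR) every entry is offset by a small positive
#' count first. Never apply this before cumulative sum scaling, which has
#' its own handling of sparsity.
#'
#' @param x a [count_table()].
#' @param value positive offset added to every entry (default 1).
#' @return A `count_table` with shifted counts.
#' @export
add_pseudocount <- function(x, value = 1) {
  stopifnot(inherits(x, "count_table"))
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    stop("'value' must be a single positive number", call. = FALSE)
  count_table(x$counts + value, taxonomy = x$taxonomy)
}
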