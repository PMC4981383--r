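# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x^2))

# matrix input guard: accepts a count_table or a plain numeric matrix
as_count_matrix <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "count_table")) return(x$counts)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("'%s' must be a count_table or a numeric matrix", arg),
       call. = FALSE)
}

assert_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite entries", arg), call. = FALSE)
  invisible(x)
}
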