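#' OTU count table
#'
#' Container for a table of non-negative OTU counts. The internal
#' orientation is fixed to samples in rows and OTUs in columns, the usual
#' statistical convention (observations in rows); QIIME-classic files,
#' which store OTUs in rows, are transposed at ingest.
#'
#' @param counts numeric matrix of non-negative counts, samples x OTUs,
#'   with unique row (sample) and column (OTU) names.
#' @param taxonomy optional named character vector of Greengenes-style
#'   lineage strings, named by OTU id.
#' @return An object of class `count_table`: a list with elements
#'   `counts` (matrix) and `taxonomy` (named character or `NULL`).
#' @seealso [read_count_table()], [filter_samples()], [tss()]
#' @export
count_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have sample (row) and OTU (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  if (any(is.na(counts)))
    stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
         call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(counts))]
    if (length(taxonomy) == 0) taxonomy <- NULL
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  total counts: %s; zeros: %.1f%%\n",
              format(sum(x$counts), big.mark = ","),
              100 * mean(x$counts == 0)))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy available for %d OTUs\n", length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Sample and OTU identifiers
#'
#' @param x a `count_table`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(as_count_matrix(x))

#' @rdname sample_ids
#' @export
otu_ids <- function(x) colnames(as_count_matrix(x))

#' Read an OTU count table
#'
#' Reads a tab-separated OTU table. QIIME-classic files (first line may be
#' `# Constructed from biom file`, header starting with `#OTU ID`, OTUs in
#' rows, optional trailing `taxonomy` column) are detected automatically
#' and transposed to the internal samples x OTUs orientation. The taxonomy
#' column, when present, is split off into the `taxonomy` field so the
#' count matrix stays purely numeric.
#'
#' @param path path to a TSV file.
#' @param orientation `"auto"` (header cell `#OTU ID` means OTUs in rows),
#'   `"samples_in_rows"` or `"otus_in_rows"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("auto", "samples_in_rows",
                                             "otus_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 2L)
  skip <- 0L
  if (length(head_lines) >= 1 && grepl("^#", head_lines[1]) &&
      !grepl("^#OTU ID\t", head_lines[1]) && length(head_lines) >= 2 &&
      grepl("^#OTU ID\t", head_lines[2]))
    skip <- 1L
  header <- strsplit(readLines(path, n = skip + 1L)[skip + 1L], "\t",
                     fixed = TRUE)[[1]]
  df <- utils::read.delim(path, skip = skip, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (orientation == "auto")
    orientation <- if (identical(header[1], "#OTU ID"))
      "otus_in_rows" else "samples_in_rows"

  row_ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if (orientation == "otus_in_rows" &&
      tolower(colnames(body)[ncol(body)]) == "taxonomy") {
    taxonomy <- stats::setNames(body[[ncol(body)]], row_ids)
    body <- body[, -ncol(body), drop = FALSE]
  }
  mat <- vapply(body, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(body)))
  if (nrow(body) == 1L) mat <- matrix(mat, nrow = 1L,
                                      dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0) {
    stop(sprintf(
      "non-numeric value '%s' at row '%s', column '%s' of %s",
      body[bad[1, 1], bad[1, 2]], row_ids[bad[1, 1]],
      colnames(body)[bad[1, 2]], path), call. = FALSE)
  }
  rownames(mat) <- row_ids
  if (orientation == "otus_in_rows") mat <- t(mat)
  count_table(mat, taxonomy = taxonomy)
}

#' Write an OTU count table in QIIME-classic layout
#'
#' Serializes the table with OTUs in rows under a `#OTU ID` header; a
#' `taxonomy` column is appended when lineages are attached. Reading the
#' file back reproduces the table exactly.
#'
#' @param x a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  m <- t(x$counts)  # OTUs in rows
  header <- c("#OTU ID", rownames(x$counts))
  body <- cbind(rownames(m),
                matrix(format(m, trim = TRUE, scientific = FALSE),
                       nrow = nrow(m)))
  if (!is.null(x$taxonomy)) {
    header <- c(header, "taxonomy")
    body <- cbind(body, unname(x$taxonomy[rownames(m)]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a TSV with columns `sample_id`, `subject_id` and `class_label`.
#' When `samples` is supplied (e.g. `sample_ids(table)`), coverage is
#' checked and a missing sample raises an error naming it. A subject with
#' repeated observations of the same class is accepted but reported as an
#' unbalanced design.
#'
#' @param path path to the metadata TSV.
#' @param samples optional character vector of sample ids that must all be
#'   present in the metadata.
#' @return A `data.frame` with character columns `sample_id`,
#'   `subject_id`, `class_label`, one row per sample.
#' @export
read_metadata <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  needed <- c("sample_id", "subject_id", "class_label")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, needed]
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (!is.null(samples)) {
    absent <- setdiff(samples, df$sample_id)
    if (length(absent))
      stop("sample(s) present in the count table but absent from the ",
           "metadata: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  cells <- table(df$subject_id, df$class_label)
  if (any(cells > 1)) {
    idx <- which(cells > 1, arr.ind = TRUE)
    message("unbalanced design: repeated subject x class cells: ",
            paste(sprintf("%s/%s (%d)", rownames(cells)[idx[, 1]],
                          colnames(cells)[idx[, 2]], cells[idx]),
                  collapse = ", "))
  }
  message(sprintf("metadata: %d samples, %d subjects, %d classes (%s)",
                  nrow(df), length(unique(df$subject_id)),
                  length(unique(df$class_label)),
                  paste(sort(unique(df$class_label)), collapse = ", ")))
  df
}
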