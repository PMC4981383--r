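# Greengenes-style lineages: "k__Bacteria; p__Firmicutes; ...".
# A rank absent from the string is NA; a rank present with an empty value
# ("p__") is stored as "" so that parse -> format is a lossless round trip.

TAX_RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
               family = "f", genus = "g", species = "s")

#' Parse Greengenes-style taxonomy lineages
#'
#' Splits semicolon-separated lineage strings into the seven canonical
#' ranks by their one-letter prefixes (`k__` ... `s__`). A token with an
#' unrecognized prefix is stored, with a warning, at the next unfilled
#' rank. A rank present but empty (`p__`) is kept as the empty string and
#' distinguished from an absent rank (`NA`).
#'
#' @param lineage character vector of lineage strings.
#' @return A `data.frame` with columns `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`, one row per input lineage.
#' @export
parse_taxonomy <- function(lineage) {
  ranks <- names(TAX_RANKS)
  out <- matrix(NA_character_, nrow = length(lineage), ncol = length(ranks),
                dimnames = list(names(lineage), ranks))
  for (i in seq_along(lineage)) {
    if (is.na(lineage[i]) || !nzchar(trimws(lineage[i]))) next
    tokens <- trimws(strsplit(lineage[i], ";", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    for (tok in tokens) {
      m <- regmatches(tok, regexec("^([A-Za-z])__(.*)$", tok))[[1]]
      if (length(m) == 3 && m[2] %in% TAX_RANKS) {
        out[i, which(TAX_RANKS == m[2])] <- m[3]
      } else {
        slot <- which(is.na(out[i, ]))[1]
        if (is.na(slot)) slot <- length(ranks)
        warning(sprintf("unknown taxonomy prefix in '%s'; stored at rank %s",
                        tok, ranks[slot]), call. = FALSE)
        out[i, slot] <- sub("^[A-Za-z]__", "", tok)
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Serialize parsed taxonomy back to lineage strings
#'
#' Inverse of [parse_taxonomy()]: emits `prefix__value` tokens for every
#' non-missing rank (including explicitly empty ranks), joined by `"; "`.
#'
#' @param tax data.frame as returned by [parse_taxonomy()].
#' @return Character vector of lineage strings.
#' @export
format_taxonomy <- function(tax) {
  ranks <- names(TAX_RANKS)
  stopifnot(all(ranks %in% colnames(tax)))
  apply(tax[, ranks, drop = FALSE], 1, function(row) {
    keep <- !is.na(row)
    paste(paste0(TAX_RANKS[keep], "__", row[keep]), collapse = "; ")
  })
}
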