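#' Contribution table of selected OTUs
#'
#' Characterises every OTU selected by a sparse PLS-DA model: its signed
#' loading weight per component, its median normalized abundance in each
#' class, and the class it contributes to — the class whose median is
#' highest. Medians are computed on the normalized matrix used for the
#' fit (TSS+CLR or CSS values), not on the within-subject matrix, where
#' abundances lose their meaning. Ties for the maximum median are not
#' broken arbitrarily: all tied classes are reported and the row is
#' flagged.
#'
#' @param model an [splsda()] fit.
#' @param normalized numeric matrix of normalized abundances (samples x
#'   OTUs) covering all model features.
#' @param labels class label per row of `normalized`.
#' @param taxonomy optional named character vector of lineage strings (or
#'   a data.frame from [parse_taxonomy()] with OTU row names).
#' @param rank taxonomy rank to report (e.g. `"family"`), when taxonomy is
#'   supplied.
#' @return A `data.frame` of class `contribution_table`, one row per
#'   (component, selected OTU), ordered within component by decreasing
#'   absolute loading: columns `otu_id`, `component`, `loading`,
#'   `rank_in_component`, `assigned_class` (tied classes joined by `"/"`),
#'   `tie`, one `median.<class>` column per class, and optionally the
#'   taxonomy rank.
#' @export
contribution_table <- function(model, normalized, labels, taxonomy = NULL,
                               rank = "family") {
  stopifnot(inherits(model, "splsda"))
  assert_matrix(normalized, "normalized")
  labels <- factor(labels)
  feats <- rownames(model$x_loadings)
  missing_feats <- setdiff(feats, colnames(normalized))
  if (length(missing_feats))
    stop("OTU(s) in the model but not in the normalized matrix: ",
         paste(utils::head(missing_feats, 5), collapse = ", "),
         call. = FALSE)
  tax_ranks <- NULL
  if (!is.null(taxonomy)) {
    tax <- if (is.data.frame(taxonomy)) taxonomy else
      parse_taxonomy(taxonomy)
    if (!rank %in% colnames(tax))
      stop("unknown taxonomy rank: ", rank, call. = FALSE)
    tax_ranks <- stats::setNames(tax[[rank]], rownames(tax))
  }
  rows <- list()
  for (h in seq_len(model$ncomp)) {
    w <- model$x_loadings[, h]
    sel <- names(w)[w != 0]
    if (!length(sel)) next
    sel <- sel[order(abs(w[sel]), decreasing = TRUE)]
    med <- vapply(levels(labels), function(k)
      apply(normalized[labels == k, sel, drop = FALSE], 2, stats::median),
      numeric(length(sel)))
    if (!is.matrix(med)) med <- matrix(med, nrow = length(sel),
                                       dimnames = list(sel, levels(labels)))
    assigned <- apply(med, 1, function(m) {
      winners <- colnames(med)[m == max(m)]
      paste(winners, collapse = "/")
    })
    tie <- grepl("/", assigned, fixed = TRUE)
    df <- data.frame(otu_id = sel, component = h,
                     loading = unname(w[sel]),
                     rank_in_component = seq_along(sel),
                     assigned_class = unname(assigned), tie = unname(tie),
                     stringsAsFactors = FALSE)
    meds <- as.data.frame(med)
    colnames(meds) <- paste0("median.", colnames(med))
    df <- cbind(df, meds, row.names = NULL)
    if (!is.null(tax_ranks)) df[[rank]] <- unname(tax_ranks[sel])
    rows[[h]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(otu_id = character(0), component = integer(0),
               loading = numeric(0), rank_in_component = integer(0),
               assigned_class = character(0), tie = logical(0))
  class(out) <- c("contribution_table", "data.frame")
  out
}

#' Write GraPhlAn annotation files for selected OTUs
#'
#' Exports the taxonomy of the selected OTUs as a GraPhlAn input tree
#' (dot-separated clade paths, one per line) plus a plain-text annotation
#' file of `clade<TAB>attribute<TAB>value` records: marker size
#' proportional to the median normalized count in the assigned class,
#' marker colour encoding the loading sign (positive = yellow, negative =
#' black), and a background colour per assigned class (ties are greyed
#' out). Rendering itself is left to GraPhlAn.
#'
#' @param contrib a [contribution_table()].
#' @param taxonomy named character vector of lineage strings by OTU id.
#' @param annot_path output path of the annotation file.
#' @param tree_path output path of the tree file (default: `annot_path`
#'   with extension `.tree.txt`).
#' @param max_marker_size marker size given to the largest median.
#' @return Invisible list with the paths written and the per-class colour
#'   map.
#' @export
export_graphlan <- function(contrib, taxonomy, annot_path,
                            tree_path = NULL,
                            max_marker_size = 40) {
  stopifnot(inherits(contrib, "contribution_table"))
  if (is.null(tree_path))
    tree_path <- paste0(sub("\\.txt$", "", annot_path), ".tree.txt")
  # one annotation record per clade: an OTU selected on several
  # components is represented by its largest-|loading| row
  contrib <- contrib[order(-abs(contrib$loading)), , drop = FALSE]
  contrib <- contrib[!duplicated(contrib$otu_id), , drop = FALSE]
  has_lineage <- contrib$otu_id %in% names(taxonomy) &
    !is.na(taxonomy[contrib$otu_id]) & nzchar(taxonomy[contrib$otu_id])
  if (any(!has_lineage)) {
    warning("skipping OTU(s) without a lineage: ",
            paste(unique(contrib$otu_id[!has_lineage]), collapse = ", "),
            call. = FALSE)
    contrib <- contrib[has_lineage, , drop = FALSE]
  }
  classes <- sort(unique(unlist(strsplit(contrib$assigned_class, "/",
                                         fixed = TRUE))))
  palette <- grDevices::hcl.colors(max(length(classes), 2L), "Dark 3")
  class_colors <- stats::setNames(palette[seq_along(classes)], classes)

  clade_of <- function(otu) {
    tokens <- trimws(strsplit(taxonomy[[otu]], ";", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(sub("^[a-z]__", "", tokens))]
    paste(c(tokens, otu), collapse = ".")
  }
  med_cols <- grep("^median\\.", colnames(contrib), value = TRUE)
  header <- "#clade\tattribute\tvalue"
  lines <- character(0)
  tree_lines <- character(0)
  if (nrow(contrib)) {
    max_med <- max(vapply(seq_len(nrow(contrib)), function(i) {
      max(as.numeric(contrib[i, med_cols])) }, numeric(1)))
    for (i in seq_len(nrow(contrib))) {
      otu <- contrib$otu_id[i]
      clade <- clade_of(otu)
      tree_lines <- c(tree_lines, clade)
      med <- max(as.numeric(contrib[i, med_cols]))
      size <- if (max_med > 0) max(1, max_marker_size * med / max_med) else 1
      marker_col <- if (contrib$loading[i] > 0) "yellow" else "black"
      bg_col <- if (contrib$tie[i]) "grey" else
        class_colors[[contrib$assigned_class[i]]]
      lines <- c(lines,
                 sprintf("%s\tclade_marker_size\t%.6g", clade, size),
                 sprintf("%s\tclade_marker_color\t%s", clade, marker_col),
                 sprintf("%s\tannotation_background_color\t%s", clade,
                         bg_col))
    }
  }
  writeLines(c(header, lines), annot_path)
  writeLines(unique(tree_lines), tree_path)
  invisible(list(annotation = annot_path, tree = tree_path,
                 class_colors = class_colors))
}

#' Per-class confidence ellipses in a 2-D score plot
#'
#' Computes, for each class, the ellipse containing a given probability
#' mass of a bivariate Gaussian fitted to the class scores: centre = class
#' mean, axes = eigenvectors of the class covariance with semi-axis
#' lengths `sqrt(lambda_i * qchisq(level, 2))`. A class whose covariance
#' is (numerically) singular is flagged as degenerate.
#'
#' @param scores numeric matrix with >= 2 columns; the first two are used.
#' @param labels class label per row; every class needs >= 3 samples.
#' @param level confidence level in (0, 1), default 0.95.
#' @return A `data.frame`, one row per class: `class`, `center_x`,
#'   `center_y`, semi-axes `a` >= `b`, `angle` (radians, orientation of
#'   the major axis) and `degenerate`.
#' @export
confidence_ellipse <- function(scores, labels, level = 0.95) {
  assert_matrix(scores, "scores")
  stopifnot(ncol(scores) >= 2, level > 0, level < 1)
  labels <- factor(labels)
  if (any(table(labels) < 3))
    stop("every class needs at least 3 samples", call. = FALSE)
  s2 <- scores[, 1:2, drop = FALSE]
  r2 <- stats::qchisq(level, df = 2)
  out <- lapply(levels(labels), function(k) {
    xk <- s2[labels == k, , drop = FALSE]
    mu <- colMeans(xk)
    S <- stats::cov(xk)
    e <- eigen(S, symmetric = TRUE)
    degenerate <- e$values[2] < 1e-12 * max(e$values[1], 1e-300)
    data.frame(class = k, center_x = mu[1], center_y = mu[2],
               a = sqrt(max(e$values[1], 0) * r2),
               b = sqrt(max(e$values[2], 0) * r2),
               angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
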