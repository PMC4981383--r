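#' Run the multivariate microbiome pipeline
#'
#' Orchestrates the full analysis: prefiltering (samples then rare OTUs),
#' normalization (TSS+CLR, TSS+ILR or CSS; a pseudocount is added on the
#' log-ratio branch only), optional within-subject decomposition, and
#' either PCA or tuned sparse PLS-DA with contribution tables, confidence
#' ellipses and GraPhlAn annotation export. Every intermediate matrix is
#' written to `out_dir` together with a machine-readable manifest (package
#' version, parameters, seed, MD5 hashes of the inputs) so a run can be
#' audited and reproduced. A failing stage aborts with the stage name;
#' files already written are kept.
#'
#' @param config a named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{input}{either `list(table =, metadata =)` paths, or
#'       `list(simulate = list(...))` with [synth_config()] arguments.}
#'     \item{filter}{`min_sample_total` (default 10) and `min_otu_prop`
#'       (default 1e-4).}
#'     \item{normalization}{`"tss-clr"` (default), `"tss-ilr"` or
#'       `"css"`.}
#'     \item{pseudocount}{offset for the log-ratio branch (default 1);
#'       rejected on the CSS branch.}
#'     \item{css}{`percentile` (default `"auto"`) and `log_base`
#'       (default 2).}
#'     \item{multilevel}{logical; decompose by `subject_id` (default
#'       `FALSE`).}
#'     \item{analysis}{`"splsda"` (default) or `"pca"`.}
#'     \item{pca}{`ncomp` (default 2).}
#'     \item{splsda}{`keepX_grid`, `max_comp`, `folds`, `repeats`,
#'       `distance`, `legacy_cv`.}
#'     \item{taxonomy_rank}{rank reported in the contribution table
#'       (default `"family"`).}
#'     \item{seed}{integer, funnels all randomness (default 1).}
#'   }
#' @param out_dir output directory, created if needed.
#' @return Invisible list with the fitted objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  norm <- config$normalization %||% "tss-clr"
  if (!norm %in% c("tss-clr", "tss-ilr", "css"))
    stop("unknown normalization: ", norm, call. = FALSE)
  if (norm == "css" && !is.null(config$pseudocount))
    stop("stage 'normalize': a pseudocount is only meaningful on the ",
         "log-ratio branch; remove it for CSS", call. = FALSE)
  analysis <- config$analysis %||% "splsda"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ## --- input -------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(config$input$simulate)) {
      cfg <- do.call(synth_config,
                     c(config$input$simulate,
                       if (is.null(config$input$simulate$seed))
                         list(seed = seed)))
      sim <- simulate_counts(cfg)
      jsonlite::write_json(sim$truth$planted,
                           file.path(out_dir, "truth.json"))
      sim[c("table", "metadata")]
    } else {
      tab <- read_count_table(config$input$table)
      md <- read_metadata(config$input$metadata,
                          samples = sample_ids(tab))
      list(table = tab, metadata = md)
    }
  })
  md <- dat$metadata[match(sample_ids(dat$table), dat$metadata$sample_id), ]

  ## --- filter ------------------------------------------------------
  filtered <- stage("filter", {
    x <- filter_samples(dat$table,
                        config$filter$min_sample_total %||% 10)
    filter_otus(x, config$filter$min_otu_prop %||% 1e-4)
  })
  md <- md[match(sample_ids(filtered), md$sample_id), ]
  write_count_table(filtered, file.path(out_dir, "filtered_counts.tsv"))

  ## --- normalize ---------------------------------------------------
  normalized <- stage("normalize", switch(norm,
    "tss-clr" = clr(tss(add_pseudocount(filtered,
                                        config$pseudocount %||% 1))),
    "tss-ilr" = ilr(tss(add_pseudocount(filtered,
                                        config$pseudocount %||% 1))),
    "css" = css(filtered, percentile = config$css$percentile %||% "auto",
                log_base = config$css$log_base %||% 2)))
  write_matrix_tsv(normalized, file.path(out_dir, "normalized.tsv"))

  ## --- multilevel --------------------------------------------------
  multilevel <- isTRUE(config$multilevel)
  Xin <- normalized
  if (multilevel) {
    decomp <- stage("multilevel",
                    within_variation(normalized, md$subject_id))
    Xin <- decomp$within
    write_matrix_tsv(Xin, file.path(out_dir, "within.tsv"))
  }

  ## --- analysis ----------------------------------------------------
  results <- list()
  if (analysis == "pca") {
    fit <- stage("pca", pca_ord(Xin, ncomp = config$pca$ncomp %||% 2))
    write_matrix_tsv(fit$scores, file.path(out_dir, "pca_scores.tsv"))
    utils::write.table(
      data.frame(component = seq_along(fit$explained),
                 explained = fit$explained),
      file.path(out_dir, "pca_explained.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$pca <- fit
  } else if (analysis == "splsda") {
    sp <- config$splsda %||% list()
    tuned <- stage("splsda", tune_splsda(
      normalized, md$class_label,
      keepX_grid = sp$keepX_grid %||% default_keepx_grid(ncol(normalized)),
      max_comp = sp$max_comp %||% 3,
      folds = sp$folds %||% 10, repeats = sp$repeats %||% 10,
      seed = seed,
      subjects = if (multilevel || isTRUE(sp$subject_folds))
        md$subject_id else NULL,
      multilevel = multilevel, legacy_cv = isTRUE(sp$legacy_cv),
      distance = sp$distance %||% "max"))
    model <- tuned$final
    write_matrix_tsv(model$x_loadings, file.path(out_dir, "loadings.tsv"))
    write_matrix_tsv(model$x_scores, file.path(out_dir, "scores.tsv"))
    utils::write.table(
      data.frame(component = seq_len(tuned$ncomp),
                 keepX = tuned$choice_keepX, error = tuned$error,
                 error_sd = tuned$error_sd),
      file.path(out_dir, "cv_error.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(tuned$error_surface,
                     file.path(out_dir, "error_surface.tsv"),
                     id_col = "component")
    contrib <- stage("interpret", contribution_table(
      model, normalized, md$class_label, taxonomy = filtered$taxonomy,
      rank = config$taxonomy_rank %||% "family"))
    utils::write.table(contrib, file.path(out_dir, "contribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(filtered$taxonomy))
      stage("interpret", export_graphlan(
        contrib, filtered$taxonomy,
        file.path(out_dir, "graphlan_annot.txt")))
    if (tuned$ncomp >= 2 && all(table(md$class_label) >= 3)) {
      ell <- stage("interpret",
                   confidence_ellipse(model$x_scores, md$class_label))
      jsonlite::write_json(ell, file.path(out_dir, "ellipses.json"),
                           dataframe = "rows", digits = NA)
    }
    results$tune <- tuned
    results$contribution <- contrib
  } else stop("unknown analysis: ", analysis, call. = FALSE)

  ## --- manifest ----------------------------------------------------
  manifest <- list(
    package = "micropls",
    version = as.character(utils::packageVersion("micropls")),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, normalization = norm, multilevel = multilevel,
    analysis = analysis, config = config,
    input_md5 = {
      paths <- as.character(unlist(config$input[c("table", "metadata")]))
      paths <- paths[!is.na(paths) & file.exists(paths)]
      if (length(paths)) as.list(tools::md5sum(paths)) else list()
    },
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
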