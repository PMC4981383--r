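#' Configuration of the repeated-measures microbiome simulator
#'
#' Describes a Dirichlet-multinomial community sampled repeatedly on the
#' same subjects across several habitats (classes). Each class has a
#' disjoint set of planted discriminative OTUs whose Dirichlet
#' concentrations are multiplied by `effect_size` in that class; each
#' subject has a log-scale random effect shared across its samples, which
#' creates the between-subject variation that the multilevel decomposition
#' removes.
#'
#' Defaults emulate a moderately deep 16S survey: 300 OTUs with a small
#' common concentration (0.1, giving sparse overdispersed compositions),
#' log-normal library sizes around 10,000 reads, 50 subjects each sampled
#' in 3 habitats, 10 planted OTUs per habitat with an 8-fold concentration
#' shift, and a subject effect standard deviation of 1 on the log scale.
#'
#' @param n_subjects subjects, each observed once per class.
#' @param n_classes habitats / body sites per subject.
#' @param n_otus total OTUs.
#' @param n_discriminative planted discriminative OTUs per class.
#' @param effect_size multiplicative concentration shift (> 1) of planted
#'   OTUs in their class.
#' @param concentration baseline Dirichlet concentration per OTU.
#' @param subject_effect_sd sd of the per-subject, per-OTU log-scale
#'   random effect (0 = no subject effect).
#' @param library_size_meanlog,library_size_sdlog log-normal parameters of
#'   the library sizes.
#' @param sparsity_target expected fraction of zero counts; a simulation
#'   whose achieved sparsity misses it by more than 0.2 warns.
#' @param seed integer seed making the draw reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 50, n_classes = 3, n_otus = 300,
                         n_discriminative = 10, effect_size = 8,
                         concentration = 0.1, subject_effect_sd = 1,
                         library_size_meanlog = log(1e4),
                         library_size_sdlog = 0.5,
                         sparsity_target = 0.6, seed = 1) {
  cfg <- list(n_subjects = n_subjects, n_classes = n_classes,
              n_otus = n_otus, n_discriminative = n_discriminative,
              effect_size = effect_size, concentration = concentration,
              subject_effect_sd = subject_effect_sd,
              library_size_meanlog = library_size_meanlog,
              library_size_sdlog = library_size_sdlog,
              sparsity_target = sparsity_target, seed = seed)
  stopifnot(n_subjects >= 1, n_classes >= 1, n_otus >= 2,
            n_discriminative >= 0, effect_size > 0, concentration > 0,
            subject_effect_sd >= 0, library_size_sdlog >= 0)
  if (n_discriminative * n_classes > n_otus)
    stop("n_discriminative * n_classes exceeds n_otus", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Simulate a sparse repeated-measures OTU count table
#'
#' Draws, for every subject and class, a composition from a Dirichlet
#' whose concentrations are the baseline, multiplied by `effect_size` for
#' the class's planted OTUs and by `exp(subject effect)` (shared across
#' all of a subject's samples), then counts from a multinomial with a
#' log-normal library size. Rows therefore sum exactly to the drawn
#' library sizes, and the same seed reproduces the table bit for bit.
#'
#' @param config a [synth_config()].
#' @return List with `table` (a [count_table()], samples x OTUs),
#'   `metadata` (data.frame with `sample_id`, `subject_id`,
#'   `class_label`) and `truth` (class `synth_truth`: per class the ids of
#'   planted OTUs and their fold change, plus the achieved sparsity).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  p <- config$n_otus
  otus <- sprintf("OTU_%04d", seq_len(p))
  classes <- paste0("site", seq_len(config$n_classes))
  planted <- stats::setNames(vector("list", config$n_classes), classes)
  if (config$n_discriminative > 0) {
    pool <- seq_len(config$n_discriminative * config$n_classes)
    for (k in seq_len(config$n_classes))
      planted[[k]] <- otus[pool[seq.int((k - 1) * config$n_discriminative +
                                          1, k * config$n_discriminative)]]
  }
  n <- config$n_subjects * config$n_classes
  counts <- matrix(0, n, p)
  sample_id <- subject_id <- class_label <- character(n)
  i <- 0
  for (s in seq_len(config$n_subjects)) {
    subj <- sprintf("subj%03d", s)
    z <- stats::rnorm(p, 0, config$subject_effect_sd)
    for (k in seq_len(config$n_classes)) {
      alpha <- rep(config$concentration, p)
      idx <- match(planted[[k]], otus)
      alpha[idx] <- alpha[idx] * config$effect_size
      alpha <- alpha * exp(z)
      comp <- stats::rgamma(p, shape = alpha, rate = 1)
      comp <- comp / sum(comp)
      size <- max(1, round(stats::rlnorm(1, config$library_size_meanlog,
                                         config$library_size_sdlog)))
      i <- i + 1
      counts[i, ] <- stats::rmultinom(1, size = size, prob = comp)
      sample_id[i] <- paste0(subj, "_", classes[k])
      subject_id[i] <- subj
      class_label[i] <- classes[k]
    }
  }
  dimnames(counts) <- list(sample_id, otus)
  achieved <- mean(counts == 0)
  if (abs(achieved - config$sparsity_target) > 0.2)
    warning(sprintf(
      "achieved sparsity %.2f differs from target %.2f by more than 0.2",
      achieved, config$sparsity_target), call. = FALSE)
  truth <- structure(list(planted = planted,
                          fold_change = stats::setNames(
                            rep(config$effect_size, config$n_classes),
                            classes),
                          sparsity = achieved),
                     class = "synth_truth")
  list(table = count_table(counts),
       metadata = data.frame(sample_id = sample_id,
                             subject_id = subject_id,
                             class_label = class_label,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Precision and recall of a selected OTU set against the planted truth
#'
#' @param selected character vector of selected OTU ids (e.g.
#'   [selected_features()]), or a list of such vectors (one per
#'   component), whose union is scored.
#' @param truth the `synth_truth` from [simulate_counts()].
#' @return List with overall `precision` and `recall` and per-class
#'   `recall` (fraction of that class's planted OTUs selected).
#' @export
evaluate_recovery <- function(selected, truth) {
  stopifnot(inherits(truth, "synth_truth"))
  sel <- unique(unlist(selected))
  all_planted <- unique(unlist(truth$planted))
  tp <- length(intersect(sel, all_planted))
  list(precision = if (length(sel)) tp / length(sel) else NA_real_,
       recall = if (length(all_planted)) tp / length(all_planted)
       else NA_real_,
       per_class_recall = vapply(truth$planted, function(pl)
         if (length(pl)) length(intersect(sel, pl)) / length(pl)
         else NA_real_, numeric(1)))
}
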