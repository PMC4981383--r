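interpret_fixture <- function(seed = 1) {
  set.seed(seed)
  n_per <- 8; p <- 10
  X <- matrix(rnorm(3 * n_per * p), 3 * n_per, p,
              dimnames = list(paste0("s", 1:(3 * n_per)),
                              paste0("OTU", 1:p)))
  y <- rep(c("oral", "skin", "stool"), each = n_per)
  X[y == "oral", 1] <- X[y == "oral", 1] + 4
  X[y == "skin", 2] <- X[y == "skin", 2] + 4
  fit <- splsda(X, y, ncomp = 2, keepX = c(3, 3))
  list(X = X, y = y, fit = fit)
}

test_that("contributions assign each selected OTU to its max-median class", {
  d <- interpret_fixture()
  ct <- contribution_table(d$fit, d$X, d$y)
  expect_s3_class(ct, "contribution_table")
  expect_true(all(ct$otu_id %in% colnames(d$X)))
  # only nonzero loadings appear, keepX rows per component
  expect_equal(unname(table(ct$component)), c(3L, 3L), ignore_attr = TRUE)
  expect_true(all(ct$loading != 0))
  # assignment equals an explicit groupby-median argmax
  for (i in seq_len(nrow(ct))) {
    med <- tapply(d$X[, ct$otu_id[i]], d$y, median)
    expect_equal(ct$assigned_class[i],
                 paste(names(med)[med == max(med)], collapse = "/"))
  }
  # rows ordered by decreasing |loading| within component
  for (h in unique(ct$component)) {
    w <- abs(ct$loading[ct$component == h])
    expect_true(all(diff(w) <= 1e-12))
    expect_equal(ct$rank_in_component[ct$component == h], seq_along(w))
  }
  # OTU shifted in class A is assigned to A: {1,2,3} vs {4,5,6} semantics
  Xsmall <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                   dimnames = list(paste0("s", 1:6), "OTU1"))
  Xsmall <- cbind(Xsmall, OTU2 = c(6, 5, 4, 3, 2, 1))
  ysmall <- rep(c("A", "B"), each = 3)
  fit2 <- splsda(Xsmall, ysmall, ncomp = 1, keepX = 2)
  ct2 <- contribution_table(fit2, Xsmall, ysmall)
  expect_equal(ct2$assigned_class[ct2$otu_id == "OTU1"], "B") # medians 2 vs 5
  expect_equal(ct2$assigned_class[ct2$otu_id == "OTU2"], "A")
})

test_that("tied medians are flagged, not broken arbitrarily", {
  # OTU1: equal medians (2 vs 2) but different means, so it still loads
  X <- matrix(c(1, 2, 9, 0, 2, 4,
                0, 0, 1, 5, 6, 7), 6, 2,
              dimnames = list(paste0("s", 1:6), c("OTU1", "OTU2")))
  y <- rep(c("A", "B"), each = 3)
  fit <- splsda(X, y, ncomp = 1, keepX = 2)
  ct <- contribution_table(fit, X, y)
  t1 <- ct[ct$otu_id == "OTU1", ]
  expect_true(t1$tie)
  expect_equal(t1$assigned_class, "A/B")
  expect_false(ct$tie[ct$otu_id == "OTU2"])
  expect_error(contribution_table(fit, X[, 2, drop = FALSE], y),
               "not in the normalized matrix")
})

test_that("graphlan export encodes sign, size and background colour", {
  d <- interpret_fixture(seed = 3)
  tax <- setNames(sprintf("k__Bacteria; p__Phylum%d; f__Family%d", 1:10, 1:10),
                  paste0("OTU", 1:10))
  ct <- contribution_table(d$fit, d$X, d$y)
  annot <- tempfile(fileext = ".txt")
  out <- export_graphlan(ct, tax, annot)
  lines <- readLines(annot)
  expect_equal(lines[1], "#clade\tattribute\tvalue")
  rec <- read.delim(text = lines[-1], header = FALSE,
                    col.names = c("clade", "attribute", "value"))
  # an OTU selected on several components is annotated once, by its
  # largest-|loading| row
  dedup <- ct[order(-abs(ct$loading)), ]
  dedup <- dedup[!duplicated(dedup$otu_id), ]
  # positive loadings yellow, negative black
  col <- rec[rec$attribute == "clade_marker_color", ]
  for (i in seq_len(nrow(dedup))) {
    expect_equal(col$value[grepl(paste0("\\.", dedup$otu_id[i], "$"),
                                 col$clade)],
                 if (dedup$loading[i] > 0) "yellow" else "black")
  }
  # marker sizes monotone in the assigned-class medians
  sizes <- rec[rec$attribute == "clade_marker_size", ]
  med_max <- apply(dedup[, grep("^median\\.", colnames(dedup))], 1, max)
  got <- vapply(dedup$otu_id, function(o)
    as.numeric(sizes$value[grepl(paste0("\\.", o, "$"), sizes$clade)]),
    numeric(1))
  expect_equal(order(got), order(med_max))
  # tree file holds one clade path per selected OTU
  expect_true(file.exists(out$tree))
  expect_equal(sort(readLines(out$tree)),
               sort(unique(sub("\\t.*", "", lines[-1]))))

  # missing lineage skipped with a warning; empty table -> header only
  expect_warning(export_graphlan(ct, tax[-1], tempfile()), "OTU1")
  empty <- ct[0, ]
  class(empty) <- class(ct)
  f0 <- tempfile()
  export_graphlan(empty, tax, f0)
  expect_equal(readLines(f0), "#clade\tattribute\tvalue")
})

test_that("confidence ellipses have chi-square geometry", {
  set.seed(5)
  scores <- cbind(rnorm(300), rnorm(300))
  labels <- rep(c("A", "B"), each = 150)
  scores[labels == "B", ] <- scores[labels == "B", ] %*%
    matrix(c(2, 0.5, 0, 1), 2) + 5
  ell <- confidence_ellipse(scores, labels, level = 0.95)
  expect_equal(nrow(ell), 2)
  expect_true(all(ell$a >= ell$b))
  # isotropic class is near-circular
  iso <- ell[ell$class == "A", ]
  expect_lt(iso$a / iso$b, 1.3)
  # axes grow monotonically with the level
  lv <- c(0.5, 0.8, 0.95, 0.99)
  areas <- vapply(lv, function(l)
    confidence_ellipse(scores, labels, l)$a[1], numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_error(confidence_ellipse(scores[c(1:3, 151:152), ],
                                  labels[c(1:3, 151:152)]),
               "at least 3")
  # degenerate covariance flagged
  degen <- cbind(1:30, (1:30) * 2)
  expect_true(confidence_ellipse(degen, rep("A", 30))$degenerate)
})
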