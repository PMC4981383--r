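---
title: "Compositional multivariate analysis and sparse PLS-DA for microbiome counts"
author: "micropls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional multivariate analysis and sparse PLS-DA for microbiome counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropls)
```

## The problem

A 16S amplicon survey yields a table of OTU counts per sample. Two
properties dominate its statistics. First, the data are *compositional*:
the library size is a sequencing artefact, so a sample carries
information only about the relative abundances — the data live on a
simplex, where covariances between raw proportions are distorted by the
unit-sum constraint. Second, the tables are *sparse and overdispersed*:
most OTUs are absent from most samples, and biological variability
exceeds multinomial noise. A third complication is the design: in body
site studies the same individuals are sampled in several habitats, and
the variation *between individuals* is typically larger than the habitat
differences of interest.

This vignette explains how the package's pieces address each point, the
parameters that matter, the design decisions taken where conventions
diverge, and what the validation on synthetic data does and does not
show.

## Prefiltering

`filter_samples(x, min_total = 10)` removes failed libraries (fewer than
10 total counts). `filter_otus(x, min_prop = 1e-4)` then removes OTUs
whose aggregate count over all remaining samples is below 0.01% of the
grand total — roughly the Illumina per-base error rate, so OTUs below
this line are plausibly sequencing artefacts. Two boundary conventions
are fixed deliberately: removal is strict-below (an OTU at exactly
0.01% is kept), and the proportion denominator is the grand total
*after* sample filtering, because the sample filter runs first. The
combined filter is idempotent and never modifies surviving values.
Rarefaction is intentionally not provided: discarding reads only adds
noise, and the normalizations below handle depth differences.

## Normalization

**TSS + log ratios.** `tss()` divides each sample by its library size.
Proportions still live on the simplex, so Euclidean methods need a
log-ratio map first:

* `clr()` — centred log-ratio, `y_j = log(x_j / g(x))` with `g(x)` the
  row's geometric mean. It keeps one coordinate per OTU (the rows merely
  become zero-sum), which is essential for feature selection: a selected
  coordinate *is* an OTU.
* `ilr()` — isometric log-ratio in pivot (sequential binary partition)
  coordinates, `y_i = sqrt(i/(i+1)) log(g(x_1..x_i)/x_{i+1})`. The p−1
  coordinates are orthonormal, so PCA on them is exactly PCA in the
  Aitchison geometry; but each coordinate mixes many OTUs, so ILR is
  used for unsupervised exploration, not selection. Any orthonormal
  log-ratio basis gives the same geometry; the pivot basis is chosen for
  determinism, and `ilr_basis(p)` exposes the contrast matrix `V` with
  `ilr(x) = clr(x) %*% t(V)`.

Log ratios require strictly positive entries. The package adds a
pseudocount (`add_pseudocount()`, default 1 on the raw counts) before
TSS on the log-ratio branch. Multiplicative zero replacement is a
defensible alternative; a count offset of 1 was chosen as the simplest
rule that preserves count semantics, and the default is a parameter, not
a constant.

**CSS.** `css()` is the cumulative-sum-scaling alternative: sample j is
scaled by `s_j`, the sum of its counts up to a chosen quantile, divided
by 1000 (a conventional reference constant, configurable), then
`log2(x + 1)`. The quantile is found by a data-driven search: per-sample
quantile curves are computed from level 0.50 upwards, and the first
level at which the median absolute deviation of the sample quantiles
around their across-sample mean changes by more than 10% relative is
used (falling back to the median when the search is degenerate).
Quantiles are computed over each sample's *positive* counts: with
typical sparsity the median over all counts is zero and every scaling
factor would degenerate. Two ambiguities are resolved as package
choices: scaling is applied to raw counts and the log taken afterwards,
and the log base defaults to 2 (`log_base` is exposed, including `NULL`
for no log). No pseudocount is ever applied on the CSS branch — the +1
inside the log handles zeros — and `run_pipeline()` rejects such a
configuration.

## Multilevel decomposition

`within_variation(X, subjects)` splits a transformed matrix into
`between` (each row replaced by its subject mean) and `within`
(deviations from the subject mean), with `within + between == X`
exactly and zero within-subject means by construction. Downstream
analyses run on the within part, which removes the subject-level
variance component. Conventions: the grand mean is *not* added back to
the within matrix (PCA/PLS centre columns anyway, so scores are
unchanged; only reported column means would differ); unbalanced designs
use plain per-subject means; a subject with a single observation is an
error unless `allow_singletons = TRUE`, in which case its within-row is
zero. The decomposition ignores any ordering of the repeated
measurements, so it is *not* suitable for time-course designs where time
itself is the object of study.

## Ordination

`pca_ord()` (a thin wrapper over `prcomp`) defaults to centring without
unit-variance scaling, because log-ratio coordinates already share a
scale. `pcoa_ord()` performs classical scaling of a dissimilarity
matrix via `cmdscale`; for non-Euclidean dissimilarities such as
Bray-Curtis (`bray_curtis()`, computed with vegan) negative eigenvalues
can appear — they are dropped and counted, with explained fractions
taken over the positive spectrum only (no Cailliez-type correction).
On Euclidean distances PCoA reproduces PCA scores up to sign, a duality
the tests verify to 1e-8.

## Sparse PLS-DA

The core classifier regresses the column-centred data `X` on the
centred dummy class matrix `Y` (one 0/1 column per class) in PLS2 mode.
Per component:

1. `M = X'Y`; initialise `(u, v)` from the dominant singular pair of `M`.
2. Iterate `u <- soft(M v)`, normalised, and `v <- M'u`, normalised,
   where `soft()` is the lasso soft-threshold that keeps exactly `keepX`
   entries: the threshold is the `(keepX+1)`-th largest |weight|,
   survivors are shrunk towards zero by it with signs kept.
3. Scores `t = X u`; both `X` and `Y` are deflated by the regression on
   `t` (`X <- X − t p'`, `Y <- Y − t d'`), which makes successive scores
   exactly orthogonal.

Numerical choices: convergence is declared when the weight vector moves
by less than `tol = 1e-6` (sup norm); the iteration converges linearly
at a rate set by the gap between the two leading singular values of
`M`, so near-degenerate problems can need over a thousand of these cheap
O(pK) iterations — the default cap is 2000 and exhausting it is an
error naming the component. The loading sign is fixed by making the
dominant entry positive, so fits are platform-deterministic. With
`keepX = p` the thresholding vanishes and the fit coincides with dense
PLS-DA; the test suite verifies equality (to 1e-8) against an
independently coded classical NIPALS oracle, and agreement with the
reference ecosystem's implementation when scaling is turned off. Exact
ties among |weights| at the threshold could yield fewer than `keepX`
nonzeros; this has measure zero for continuous data and is not handled
specially.

The dummy `Y` is centred but not variance-scaled, so with unbalanced
classes larger classes carry more weight in the covariance; balanced
error rates are reported alongside overall error for this reason.

**Prediction** (`predict()`): new rows are centred with the training
means and projected through `W (P'W)^{-1}`, which absorbs the
sequential deflation; per cumulative component count, `"max"` takes the
argmax of the predicted dummy values (the default, matching the
reference ecosystem), `"centroid"` the nearest class centroid in score
space, `"mahalanobis"` the same under the pooled within-class score
covariance.

**Cross-validation** (`perf_splsda()`): stratified k-fold, repeated;
within each repeat every sample is predicted exactly once and the
overall error, balanced error rate and per-class errors are recorded
for each component count, then averaged across repeats. Fold draws use
`seed + r` in repeat `r`, so a seed fully reproduces the result. A
training split that loses an entire class triggers a redraw (at most
10). When `subjects` is given, folds are drawn at the subject level so
repeated measures of one individual never straddle a split. With
`multilevel = TRUE` the within-decomposition is *recomputed on each
training split*, and the test split is decomposed with its own subject
means — no subject-mean information crosses the split. A
`legacy_cv = TRUE` flag instead decomposes once and folds by rows,
reproducing the simpler behaviour of decompose-then-CV at the cost of
some leakage of subject means across folds.

**Tuning** (`tune_splsda()`): a sequential, componentwise grid search.
With earlier components fixed, the grid (default 5–50 by 5 and 60–200
by 20, capped at p — spanning the selection sizes typical for
microbiome signatures) is evaluated by CV for the current component;
the minimiser of the mean error wins, ties going to the smallest
`keepX` (parsimony). A further component is kept only while it lowers
the mean error by more than one standard deviation of the candidate
error — a one-sd rule that stops at the knee of the error curve. The
final model is refit on the full data with the chosen settings. Because
every grid value is evaluated with the same seed, all candidates see
identical folds. CV error estimates from few repeats are noisy and the
parsimony tie-break will then occasionally pick a too-small `keepX`;
around ten repeats stabilises the minimiser at the problem sizes used
here (the convention of many repeated 10-fold splits is retained for
real analyses).

## Interpretation outputs

`contribution_table()` reports, per component, each selected OTU's
signed loading and its median *normalized* abundance per class — medians
are taken on the TSS+CLR or CSS matrix used for the fit, never on the
within-matrix, where abundances lose meaning. The OTU is assigned to
the class with the highest median; exact ties are preserved (all tied
classes reported, row flagged) rather than broken arbitrarily, since
tie frequency is itself informative (CSS-normalized data produce many).
Rows are ordered by decreasing |loading| within component, the order
used by contribution barplots.

`export_graphlan()` writes the annotation and tree files a GraPhlAn
cladogram needs: marker size proportional to the median abundance in
the assigned class, marker colour yellow for positive and black for
negative loadings, background colour per assigned class with ties
greyed out. An OTU selected on several components is annotated once, by
its largest-|loading| row, since a clade can carry only one marker.
Rendering is GraPhlAn's job; the package only emits the text inputs.

`confidence_ellipse()` fits per-class bivariate Gaussians to the first
two score columns; semi-axes are `sqrt(lambda_i * qchisq(level, 2))`.
The 95% ellipse of a Gaussian cloud should contain ~95% of its points,
and a Monte-Carlo test at n = 10,000 verifies coverage within ±0.02.

## The synthetic generator and what the tests show

`simulate_counts()` draws, for each subject and class, a composition
from a Dirichlet and counts from a multinomial — the standard
overdispersed null for microbiome counts — with three structural knobs:

* *Planted signal*: each class has a disjoint set of
  `n_discriminative` OTUs whose concentration is multiplied by
  `effect_size` in that class.
* *Subject effect*: one `N(0, subject_effect_sd^2)` deviate per subject
  and OTU, applied on log-concentrations and shared across that
  subject's samples — exactly the between-subject structure the
  multilevel step removes.
* *Sparsity/overdispersion*: a small baseline concentration (default
  0.1 per OTU) yields the zero fractions (~50–70%) typical of real
  tables; library sizes are log-normal around 10,000 reads.

Defaults (50 subjects × 3 classes, 300 OTUs, 10 planted per class,
effect size 8, subject sd 1, seed-reproducible) describe a
moderate-sized, strongly-signalled body-site study; they are the
conditions under which the validation suite runs, chosen once as
realistic for a proof-of-recovery, not adjusted per test. "Large"
subject effects in the multilevel-benefit checks mean `sd = 2`, twice
the default.

What passing tests show: the algebra is right (log-ratio geometry,
decomposition identities, dense-PLS equivalence, exact sparsity), CV is
calibrated (chance error on permuted labels, at a sample size where the
Monte-Carlo fluctuation sits well inside the ±0.05 band), and under
Dirichlet-multinomial data with planted effects the tuned model
recovers the planted OTUs (precision/recall ≥ 0.8) while the multilevel
CV error beats the non-multilevel one under strong subject effects.
What they do not show: real communities have phylogenetic and
co-occurrence correlation structure, taxon-specific overdispersion, and
batch effects that the exchangeable Dirichlet baseline lacks; recovery
rates on this generator are therefore an upper bound on what identical
settings achieve on real data, and error rates on real studies must be
estimated by the same cross-validation machinery, not carried over.

## Pipeline, provenance, limitations

`run_pipeline()` chains filter → pseudocount → normalize → (multilevel)
→ PCA or tune+sPLS-DA → interpretation from a single config (YAML or
list), writing every intermediate matrix and a `manifest.json` with the
package version, full parameters, seed and MD5 hashes of the input
files; provenance is recorded in the manifest rather than encoded in
file names. A failing stage aborts with the stage name and keeps
partial outputs. Problem sizes in the shipped tests and validation
script (5–10 folds, 2–20 repeats, tables up to 150 × 300) were chosen
as the smallest sizes at which the statistical claims are sharp.

Known limitations: no Unifrac distances (they need a phylogenetic tree;
`pcoa_ord()` accepts any precomputed dissimilarity), no time-course
modelling, no multi-omics integration, BIOM-HDF5 not read (QIIME-classic
TSV is the interchange format), and the Mahalanobis prediction rule is
the naive pooled-covariance version.
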