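# Cross-cohort comparability: shared prevalent genera, per-taxon
# distribution shifts, and whether samples cluster by project rather than
# phenotype — the practical caution for meta-analyses across studies with
# different protocols.

#' Shared prevalent taxa of two cohorts
#'
#' A taxon is "prevalent" in a cohort when present in at least
#' `prevalence_threshold` of its samples. Both cohorts should be rarefied
#' to a common depth first. The overlap is reported both as Jaccard
#' (`|A n B| / |A u B|`) and relative to cohort A (`|A n B| / |A|`), since
#' either denominator is defensible.
#'
#' @param tableA,tableB cohort [taxon_table()]s.
#' @param prevalence_threshold prevalence cutoff, default 0.5.
#' @return list: `prevalent_a`, `prevalent_b`, `jaccard`, `frac_of_a`.
#' @export
shared_prevalent_genera <- function(tableA, tableB, prevalence_threshold = 0.5) {
  if (nrow(tableA) == 0 || nrow(tableB) == 0) .fail("empty cohort")
  prev_set <- function(tb) {
    prev <- colMeans(unclass_tt(tb) > 0)
    colnames(tb)[prev >= prevalence_threshold]
  }
  a <- prev_set(tableA); b <- prev_set(tableB)
  uni <- union(a, b)
  list(prevalent_a = a, prevalent_b = b,
       jaccard = if (length(uni)) length(intersect(a, b)) / length(uni) else NA_real_,
       frac_of_a = if (length(a)) length(intersect(a, b)) / length(a) else NA_real_)
}

#' Per-taxon distribution shift between cohorts
#'
#' Two-sided Wilcoxon rank-sum test on the taxon's relative abundances in
#' the two cohorts (mid-ranked ties; exact enumeration for small tie-free
#' samples, normal approximation with continuity correction otherwise, as
#' in [stats::wilcox.test()]). All values tied across both cohorts gives
#' p = 1.
#'
#' @param tableA,tableB cohort [taxon_table()]s.
#' @param taxon taxon label (must occur in the union taxon set).
#' @return list: `p`, `statistic` (rank-sum W), `n_a`, `n_b`.
#' @export
taxon_shift_test <- function(tableA, tableB, taxon) {
  if (nrow(tableA) == 0 || nrow(tableB) == 0) .fail("empty cohort")
  if (!(taxon %in% union(colnames(tableA), colnames(tableB))))
    .fail("taxon %s absent from both cohorts", taxon)
  ab <- function(tb) {
    if (taxon %in% colnames(tb)) relative_abundance(tb)[, taxon]
    else rep(0, nrow(tb))
  }
  x <- ab(tableA); y <- ab(tableB)
  if (length(unique(c(x, y))) == 1)
    return(list(p = 1, statistic = NA_real_, n_a = length(x), n_b = length(y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_a = length(x), n_b = length(y))
}

#' Hierarchical clustering of samples with cohort purity
#'
#' Complete-linkage agglomerative clustering on the Bray-Curtis
#' dissimilarity matrix ([stats::hclust()], which breaks merge-height ties
#' by smallest index). Purity is the fraction of samples whose cluster
#' (tree cut at `k` clusters) carries their own cohort as its majority
#' label. The dendrogram can be serialised to Newick with branch heights
#' via [ape::as.phylo()].
#'
#' @param table a [taxon_table()] at a common depth, >= 4 samples.
#' @param labeling named character vector sample_id -> cohort label.
#' @param k clusters for the purity cut, default 2.
#' @param newick_path optional path; when given the tree is written as
#'   Newick.
#' @return list: `hclust`, `clusters` (cut assignment), `purity`.
#' @export
cluster_samples <- function(table, labeling, k = 2, newick_path = NULL) {
  stopifnot(nrow(table) >= 4)
  if (!all(rownames(table) %in% names(labeling)))
    .fail("unlabelled sample(s): %s",
          paste(setdiff(rownames(table), names(labeling)), collapse = ", "))
  d <- stats::as.dist(bray_curtis(table))
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, k = k)
  lab <- labeling[rownames(table)]
  majority <- vapply(split(lab, cl), function(v)
    names(sort(table(v), decreasing = TRUE))[1], character(1))
  purity <- mean(majority[as.character(cl)] == lab)
  if (!is.null(newick_path))
    ape::write.tree(ape::as.phylo(hc), file = newick_path)
  list(hclust = hc, clusters = cl, purity = purity)
}
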