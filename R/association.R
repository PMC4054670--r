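# Cross-habitat association structure: Spearman correlation of paired
# alpha diversity, Mantel correlation of Bray-Curtis matrices, two-visit
# temporal stability, and cross-habitat tracking of a dominant taxon.
# Visit-1 samples are used for all cross-sectional analyses.

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(a, b) = 1 - 2 \sum_j \min(x_{aj}, x_{bj}) / (N_a + N_b)} on the
#' (typically rarefied) counts; computed with [vegan::vegdist()].
#'
#' @param table a [taxon_table()] with positive read totals.
#' @return symmetric numeric matrix in [0, 1] with zero diagonal and the
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  nt <- read_totals(table)
  if (any(nt == 0))
    .fail("zero-read sample(s): %s", paste(rownames(table)[nt == 0], collapse = ", "))
  as.matrix(vegan::vegdist(unclass_tt(table), method = "bray"))
}

#' Mantel correlation of two distance matrices
#'
#' r is the Pearson correlation of the off-diagonal upper triangles; the
#' one-sided p-value is `(1 + #{permuted r >= observed}) / (1 + n_permutations)`
#' under random row/column relabelling of `dB`.
#'
#' @param dA,dB symmetric distance matrices over the same samples in the
#'   same order (dimnames checked when present).
#' @param n_permutations number of permutations, default 999.
#' @param seed integer seed.
#' @return list with `r` and `p`.
#' @export
mantel_test <- function(dA, dB, n_permutations = 999, seed = 1) {
  dA <- as.matrix(dA); dB <- as.matrix(dB)
  if (!all(dim(dA) == dim(dB))) .fail("distance matrices differ in size")
  if (!is.null(rownames(dA)) && !is.null(rownames(dB)) &&
      !identical(rownames(dA), rownames(dB)))
    .fail("distance matrices are over different samples")
  n <- nrow(dA)
  if (n < 4) .fail("need >= 4 samples for a Mantel test")
  ut <- upper.tri(dA)
  x <- dA[ut]
  r_obs <- stats::cor(x, dB[ut])
  count <- with_seed(derive_seed(seed, "mantel"), {
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      p <- sample.int(n)
      if (stats::cor(x, dB[p, p][ut]) >= r_obs) hits <- hits + 1L
    }
    hits
  })
  list(r = r_obs, p = (1 + count) / (1 + n_permutations))
}

# Subjects having a visit-1 sample in the given habitat table; returns a
# named character vector subject -> sample_id.
subjects_v1 <- function(table, metadata) {
  md <- metadata[metadata$sample_id %in% rownames(table) & metadata$visit == 1, ]
  stats::setNames(md$sample_id, md$subject_id)
}

#' Paired-habitat diversity association
#'
#' For subjects sampled in both habitats (visit 1), both habitats' samples
#' are rarefied to the minimum read count over the paired samples, then
#' (alpha) per-subject richness is correlated by Spearman with mid-ranked
#' ties, and (beta) the two Bray-Curtis matrices are compared by Mantel
#' correlation. Fewer than 3 shared subjects yields a flagged undefined
#' result rather than propagated NaN.
#'
#' @param tableA,tableB [taxon_table()]s of the two habitats.
#' @param metadata a [sample_metadata()] covering both tables.
#' @param seed integer seed (rarefaction and Mantel permutations).
#' @param n_permutations Mantel permutations, default 999.
#' @return list: `n_shared_subjects`, `depth`, `spearman_richness`,
#'   `mantel_r`, `mantel_p`, `defined`.
#' @export
habitat_association <- function(tableA, tableB, metadata, seed = 1,
                                n_permutations = 999) {
  sa <- subjects_v1(tableA, metadata)
  sb <- subjects_v1(tableB, metadata)
  shared <- intersect(names(sa), names(sb))
  if (length(shared) < 3) {
    return(list(n_shared_subjects = length(shared), depth = NA_integer_,
                spearman_richness = NA_real_, mantel_r = NA_real_,
                mantel_p = NA_real_, defined = FALSE))
  }
  ma <- taxon_table(unclass_tt(tableA)[sa[shared], , drop = FALSE])
  mb <- taxon_table(unclass_tt(tableB)[sb[shared], , drop = FALSE])
  depth <- min(read_totals(ma), read_totals(mb))
  ra <- rarefy_table(ma, depth = depth, seed = seed)
  rb <- rarefy_table(mb, depth = depth, seed = seed)
  rich_a <- apply(unclass_tt(ra), 1, richness)
  rich_b <- apply(unclass_tt(rb), 1, richness)
  rho <- suppressWarnings(stats::cor(rich_a, rich_b, method = "spearman"))
  mt <- if (length(shared) >= 4) {
    # both matrices are ordered by the shared subjects; relabel so the
    # Mantel id check compares subjects, not habitat-specific sample ids
    da <- bray_curtis(ra); db <- bray_curtis(rb)
    dimnames(da) <- dimnames(db) <- list(shared, shared)
    mantel_test(da, db, n_permutations = n_permutations, seed = seed)
  } else list(r = NA_real_, p = NA_real_)
  list(n_shared_subjects = length(shared), depth = depth,
       spearman_richness = rho, mantel_r = mt$r, mantel_p = mt$p,
       defined = TRUE)
}

#' Two-visit temporal stability
#'
#' For each subject with samples at both visits (one habitat), both visits
#' are rarefied to a common depth and the Spearman correlation of the
#' relative abundances is computed across the union of taxa observed in
#' either visit (zeros retained for one-sided absences). Subjects missing
#' a visit are skipped with a message.
#'
#' @param table a [taxon_table()] containing both visits' samples.
#' @param metadata a [sample_metadata()].
#' @param habitat habitat to evaluate.
#' @param depth common rarefaction depth; default the minimum read total
#'   over the habitat's paired samples.
#' @param seed integer seed.
#' @return data.frame: subject_id, spearman, interval_days.
#' @export
temporal_stability <- function(table, metadata, habitat, depth = NULL, seed = 1) {
  md <- metadata[metadata$habitat == habitat & metadata$sample_id %in% rownames(table), ]
  v1 <- md[md$visit == 1, ]; v2 <- md[md$visit == 2, ]
  shared <- intersect(v1$subject_id, v2$subject_id)
  skipped <- setdiff(union(v1$subject_id, v2$subject_id), shared)
  if (length(skipped))
    message(sprintf("temporal_stability: %d subject(s) missing a visit skipped", length(skipped)))
  if (!length(shared))
    return(data.frame(subject_id = character(), spearman = numeric(),
                      interval_days = integer(), stringsAsFactors = FALSE))
  ids <- c(v1$sample_id[match(shared, v1$subject_id)],
           v2$sample_id[match(shared, v2$subject_id)])
  sub <- taxon_table(unclass_tt(table)[ids, , drop = FALSE])
  if (is.null(depth)) depth <- min(read_totals(sub))
  rt <- relative_abundance(rarefy_table(sub, depth = depth, seed = seed))
  n <- length(shared)
  rho <- vapply(seq_len(n), function(i) {
    a <- rt[i, ]; b <- rt[n + i, ]
    keep <- a > 0 | b > 0
    if (sum(keep) == 1) return(1) # both visits all-in on the same taxon
    suppressWarnings(stats::cor(a[keep], b[keep], method = "spearman"))
  }, numeric(1))
  data.frame(subject_id = shared, spearman = rho,
             interval_days = v1$interval_days[match(shared, v1$subject_id)],
             stringsAsFactors = FALSE)
}

#' Correlation of inter-visit interval with temporal stability
#'
#' Spearman correlation between the days separating a subject's two visits
#' and that subject's between-visit community correlation. Subjects with
#' missing intervals are dropped (count reported); a constant interval
#' vector has no rank variance and is flagged undefined.
#'
#' @param stability data.frame from [temporal_stability()].
#' @return list: `rho`, `n`, `n_dropped`, `defined`.
#' @export
interval_vs_stability <- function(stability) {
  ok <- !is.na(stability$interval_days) & !is.na(stability$spearman)
  n_dropped <- sum(!ok)
  s <- stability[ok, , drop = FALSE]
  if (nrow(s) < 3 || stats::sd(s$interval_days) == 0 || stats::sd(s$spearman) == 0)
    return(list(rho = NA_real_, n = nrow(s), n_dropped = n_dropped, defined = FALSE))
  list(rho = stats::cor(s$interval_days, s$spearman, method = "spearman"),
       n = nrow(s), n_dropped = n_dropped, defined = TRUE)
}

#' Cross-habitat abundance tracking of a dominant taxon
#'
#' For a taxon dominant in its home habitat, computes for every other
#' habitat the Spearman correlation (over subjects sampled in both) between
#' the subject's home-habitat relative abundance of the taxon and its
#' relative abundance in that habitat. The home habitat correlates with
#' itself at exactly 1.
#'
#' @param taxon taxon label.
#' @param home_habitat habitat where the taxon is at home.
#' @param tables named list of per-habitat [taxon_table()]s.
#' @param metadata a [sample_metadata()].
#' @return data.frame: habitat, n_shared_subjects, spearman, defined.
#' @export
dominant_taxon_cross_correlation <- function(taxon, home_habitat, tables,
                                             metadata) {
  home <- tables[[home_habitat]]
  if (is.null(home) || !(taxon %in% colnames(home)) ||
      sum(unclass_tt(home)[, taxon]) == 0)
    .fail("taxon %s not present in home habitat %s", taxon, home_habitat)
  sh <- subjects_v1(home, metadata)
  ab_home <- relative_abundance(home)[, taxon]
  rows <- lapply(names(tables), function(h) {
    tb <- tables[[h]]
    st <- subjects_v1(tb, metadata)
    shared <- intersect(names(sh), names(st))
    if (!(taxon %in% colnames(tb)) || sum(unclass_tt(tb)[, taxon]) == 0 ||
        length(shared) < 3)
      return(data.frame(habitat = h, n_shared_subjects = length(shared),
                        spearman = NA_real_, defined = FALSE))
    x <- ab_home[sh[shared]]
    y <- relative_abundance(tb)[st[shared], taxon]
    rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    data.frame(habitat = h, n_shared_subjects = length(shared),
               spearman = rho, defined = !is.na(rho))
  })
  do.call(rbind, rows)
}
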