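# Alpha diversity, habitat comparisons, accumulation and rank-abundance
# curves. Shannon uses the natural log throughout.

#' Observed richness of one sample
#'
#' @param counts non-negative numeric vector.
#' @return number of taxa with count > 0.
#' @export
richness <- function(counts) {
  sum(counts > 0)
}

#' Shannon index of one sample (natural log)
#'
#' \eqn{H = -\sum_{j: p_j > 0} p_j \ln p_j} on the relative abundances.
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) .fail("zero-read sample")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Per-sample diversity summary
#'
#' @param table a [taxon_table()].
#' @param metadata optional [sample_metadata()] supplying the habitat
#'   grouping.
#' @param include_unclassified keep "*:unclassified" bins in richness and
#'   Shannon? Default `FALSE` (they are classifier artefacts, not taxa).
#' @return data.frame: sample_id, richness, shannon, and habitat if
#'   metadata was given.
#' @export
diversity_summary <- function(table, metadata = NULL,
                              include_unclassified = FALSE) {
  m <- unclass_tt(table)
  if (!include_unclassified)
    m <- m[, !grepl(":unclassified$", colnames(m)), drop = FALSE]
  out <- data.frame(sample_id = rownames(m),
                    richness = apply(m, 1, richness),
                    shannon = apply(m, 1, shannon),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(metadata))
    out$habitat <- metadata$habitat[match(out$sample_id, metadata$sample_id)]
  out
}

#' All-pairs group comparison with Bonferroni correction
#'
#' Welch two-sample t-tests on every unordered pair of groups; p-values are
#' multiplied by the number of pairs and capped at 1 (Bonferroni). Pairs
#' where either group has fewer than 2 samples are reported as `NA` rather
#' than dropped.
#'
#' @param values numeric vector of per-sample statistics.
#' @param groups group label per sample.
#' @return list: `p_adjusted` (symmetric matrix, unit diagonal by
#'   convention), `p_raw`, `statistic` (t statistics, upper triangle).
#' @export
pairwise_group_tests <- function(values, groups) {
  groups <- as.character(groups)
  g <- sort(unique(groups))
  if (length(g) < 2) .fail("need >= 2 groups")
  n <- length(g)
  praw <- tstat <- matrix(NA_real_, n, n, dimnames = list(g, g))
  n_pairs <- choose(n, 2)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- values[groups == g[i]]; b <- values[groups == g[j]]
    if (length(a) >= 2 && length(b) >= 2 &&
        (stats::sd(a) > 0 || stats::sd(b) > 0)) {
      tt <- stats::t.test(a, b)
      praw[i, j] <- praw[j, i] <- tt$p.value
      tstat[i, j] <- tstat[j, i] <- unname(tt$statistic)
    } else if (length(a) >= 2 && length(b) >= 2) {
      # both groups constant: identical -> p = 1, different -> p = 0
      praw[i, j] <- praw[j, i] <- if (mean(a) == mean(b)) 1 else 0
      tstat[i, j] <- tstat[j, i] <- if (mean(a) == mean(b)) 0 else Inf
    }
  }
  padj <- pmin(praw * n_pairs, 1)
  diag(padj) <- diag(praw) <- 1
  list(p_adjusted = padj, p_raw = praw, statistic = tstat, n_pairs = n_pairs)
}

#' Taxon accumulation curve
#'
#' For each random permutation of sample order, step s records the number
#' of distinct taxa present in the first s samples (only new taxa are added
#' at each step); the curve is the per-step mean and SD over permutations.
#' The final step equals the pooled richness for every permutation.
#' Delegates to [vegan::specaccum()] (`method = "random"`).
#'
#' @param table a [taxon_table()].
#' @param n_permutations number of random orderings, default 500.
#' @param seed integer seed.
#' @return list: `n_samples_axis`, `mean_richness`, `sd_richness`,
#'   `n_permutations`.
#' @export
accumulation_curve <- function(table, n_permutations = 500, seed = 1) {
  m <- unclass_tt(table)
  stopifnot(nrow(m) >= 1)
  if (nrow(m) == 1) {
    return(list(n_samples_axis = 1L, mean_richness = richness(m[1, ]),
                sd_richness = 0, n_permutations = n_permutations))
  }
  acc <- with_seed(derive_seed(seed, "specaccum"),
                   vegan::specaccum(m, method = "random",
                                    permutations = n_permutations))
  list(n_samples_axis = acc$sites, mean_richness = as.numeric(acc$richness),
       sd_richness = as.numeric(acc$sd), n_permutations = n_permutations)
}

#' Rank-abundance curve of a habitat
#'
#' Reads are pooled over all samples, normalised to relative abundance, and
#' sorted from most to least abundant; ties are broken by taxon label for
#' determinism. Taxa with zero pooled reads are dropped.
#'
#' @param table a [taxon_table()] with at least one read.
#' @return data.frame: rank, taxon, abundance (non-increasing, sums to 1).
#' @export
rank_abundance_curve <- function(table) {
  m <- unclass_tt(table)
  tot <- colSums(m)
  if (sum(tot) == 0) .fail("table has no reads")
  ab <- tot / sum(tot)
  ord <- order(-ab, colnames(m))
  ab <- ab[ord]
  ab <- ab[ab > 0]
  data.frame(rank = seq_along(ab), taxon = names(ab),
             abundance = unname(ab), stringsAsFactors = FALSE)
}
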