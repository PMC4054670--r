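# Prevalence-abundance structure: which taxa are cosmopolitan (found in
# most subjects) versus endemic (abundant in a subject subset), how
# detection depends on sequencing depth, the cross-habitat shared-taxon
# census, and per-taxon variation quantiles.

#' Per-taxon prevalence and carrier abundance
#'
#' Prevalence is the fraction of samples with at least one read of the
#' taxon (no minimum-abundance floor). Mean relative abundance and its
#' standard error are computed over carrier samples only — the abundance a
#' subject experiences given the taxon is there.
#'
#' @param table a [taxon_table()] with positive read totals.
#' @return data.frame: taxon, prevalence, mean_abundance, abundance_se,
#'   n_carriers.
#' @export
prevalence_abundance <- function(table) {
  m <- unclass_tt(table)
  ra <- relative_abundance(table)
  prev <- colMeans(m > 0)
  stats_j <- vapply(seq_len(ncol(m)), function(j) {
    carriers <- ra[m[, j] > 0, j]
    if (!length(carriers)) return(c(NA_real_, NA_real_, 0))
    se <- if (length(carriers) > 1) stats::sd(carriers) / sqrt(length(carriers)) else 0
    c(mean(carriers), se, length(carriers))
  }, numeric(3))
  data.frame(taxon = colnames(m), prevalence = unname(prev),
             mean_abundance = stats_j[1, ], abundance_se = stats_j[2, ],
             n_carriers = as.integer(stats_j[3, ]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Prevalence as a function of rarefaction depth
#'
#' Rarefies the table to each depth (shared seed scheme) and recomputes
#' per-taxon prevalence. Deeper sequencing detects rare taxa in more
#' subjects, so prevalence rises with depth. The summary `mean_fold_change`
#' averages prevalence(max depth) / prevalence(min depth) over taxa
#' detected at the minimum depth; taxa undetected there are excluded from
#' the ratio (their count is reported).
#'
#' @param table a [taxon_table()]; all samples need `>= max(depths)` reads.
#' @param depths read depths, default `c(1000, 3000, 6000, 9000)`.
#' @param seed integer seed.
#' @return list: `prevalence` (taxa x depths matrix), `mean_fold_change`,
#'   `n_excluded` (taxa absent at the minimum depth).
#' @export
prevalence_vs_depth <- function(table, depths = c(1000, 3000, 6000, 9000),
                                seed = 1) {
  nt <- read_totals(table)
  if (any(nt < max(depths)))
    .fail("samples below max depth %d: %s", max(depths),
          paste(rownames(table)[nt < max(depths)], collapse = ", "))
  depths <- sort(depths)
  prev <- vapply(depths, function(d) {
    rt <- rarefy_table(table, depth = d, seed = derive_seed(seed, "prevdepth", d))
    colMeans(unclass_tt(rt) > 0)
  }, numeric(ncol(table)))
  colnames(prev) <- as.character(depths)
  rownames(prev) <- colnames(table)
  at_min <- prev[, 1] > 0
  fold <- prev[at_min, ncol(prev)] / prev[at_min, 1]
  list(prevalence = prev,
       mean_fold_change = if (any(at_min)) mean(fold) else NA_real_,
       n_excluded = sum(!at_min))
}

#' Cross-habitat shared-taxon census
#'
#' A taxon is "present" in a habitat if it has at least one read in at
#' least one of the habitat's samples. Returns, per taxon, the set of
#' habitats where it is present, and the number of taxa present in every
#' habitat (the cosmopolitan core).
#'
#' @param tables named list of per-habitat [taxon_table()]s.
#' @return list: `membership` (taxa x habitats logical matrix),
#'   `n_habitats` (per-taxon habitat count), `core_taxa` (labels present
#'   everywhere), `n_core`.
#' @export
shared_taxa_census <- function(tables) {
  stopifnot(length(tables) >= 1, !is.null(names(tables)))
  all_taxa <- sort(unique(unlist(lapply(tables, colnames))))
  membership <- vapply(tables, function(tb) {
    present <- colSums(unclass_tt(tb)) > 0
    all_taxa %in% colnames(tb)[present]
  }, logical(length(all_taxa)))
  rownames(membership) <- all_taxa
  core <- all_taxa[rowSums(membership) == length(tables)]
  list(membership = membership, n_habitats = rowSums(membership),
       core_taxa = core, n_core = length(core))
}

#' Relative-abundance quantiles of the leading taxa
#'
#' Taxa are ranked by mean relative abundance over samples; for the top
#' `top_n`, the min, lower quartile, median, upper quartile, and max of the
#' per-sample relative abundance (zeros included) are reported. Quantiles
#' use the median-unbiased convention (`type = 8`).
#'
#' @param table a [taxon_table()] with positive read totals.
#' @param top_n number of taxa to report, default 20 (truncated to K with
#'   a message if larger).
#' @return data.frame: taxon, mean_abundance, min, q25, median, q75, max.
#' @export
taxon_quantiles <- function(table, top_n = 20) {
  ra <- relative_abundance(table)
  if (top_n > ncol(ra)) {
    message(sprintf("top_n truncated from %d to %d taxa", top_n, ncol(ra)))
    top_n <- ncol(ra)
  }
  mean_ab <- colMeans(ra)
  top <- order(-mean_ab, colnames(ra))[seq_len(top_n)]
  q <- t(apply(ra[, top, drop = FALSE], 2, stats::quantile,
               probs = c(0, 0.25, 0.5, 0.75, 1), type = 8, names = FALSE))
  data.frame(taxon = colnames(ra)[top], mean_abundance = mean_ab[top],
             min = q[, 1], q25 = q[, 2], median = q[, 3], q75 = q[, 4],
             max = q[, 5], stringsAsFactors = FALSE, row.names = NULL)
}
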