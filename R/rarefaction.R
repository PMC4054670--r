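# Depth standardisation: subsampling reads without replacement so that
# between-sample comparisons are not driven by sequencing depth.

#' Subsample one sample's counts without replacement
#'
#' Draws `depth` reads uniformly without replacement from the sample's read
#' pool, so each taxon's subsampled count follows the multivariate
#' hypergeometric distribution. Deterministic given `seed`.
#'
#' @param counts non-negative integer vector.
#' @param depth number of reads to retain; must not exceed `sum(counts)`.
#' @param seed integer seed.
#' @return integer vector summing exactly to `depth`, elementwise at most
#'   `counts`.
#' @export
rarefy_sample <- function(counts, depth, seed) {
  counts <- as.integer(counts)
  total <- sum(counts)
  if (depth > total)
    .fail("depth %d exceeds available reads %d", depth, total)
  if (depth == total) return(counts)
  k <- length(counts)
  out <- with_seed(seed, {
    pool <- rep.int(seq_len(k), counts)
    tabulate(pool[sample.int(total, depth)], nbins = k)
  })
  out <- as.integer(out)
  names(out) <- names(counts)
  out
}

#' Rarefy every sample of a table to a common depth
#'
#' Each sample is subsampled independently without replacement; per-sample
#' seeds are derived from `seed` and the sample id, so the draw for a given
#' sample does not depend on which other samples are present. All samples
#' must already have at least `depth` reads (use [filter_min_reads()]
#' first).
#'
#' @param table a [taxon_table()].
#' @param depth common post-subsampling read total, default 1000.
#' @param seed integer seed.
#' @return a [taxon_table()] with attributes `depth` and `seed`; every row
#'   sums to `depth`.
#' @export
rarefy_table <- function(table, depth = 1000, seed = 1) {
  stopifnot(inherits(table, "taxon_table"))
  nt <- read_totals(table)
  if (any(nt < depth))
    .fail("samples below depth %d: %s", depth,
          paste(rownames(table)[nt < depth], collapse = ", "))
  m <- unclass_tt(table)
  out <- t(vapply(rownames(m), function(s) {
    rarefy_sample(m[s, ], depth, derive_seed(seed, "rarefy", s))
  }, integer(ncol(m))))
  colnames(out) <- colnames(m)
  res <- taxon_table(out)
  attr(res, "depth") <- as.integer(depth)
  attr(res, "seed") <- as.integer(seed)
  res
}

#' Convert counts to relative abundances
#'
#' Each row is divided by its read total (after any subsampling), so rows
#' sum to 1.
#'
#' @param table a [taxon_table()] with strictly positive read totals.
#' @return numeric matrix of row-normalised proportions.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  nt <- read_totals(table)
  if (any(nt == 0))
    .fail("zero-read sample(s): %s", paste(rownames(table)[nt == 0], collapse = ", "))
  sweep(unclass_tt(table), 1, nt, "/")
}
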