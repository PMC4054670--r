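# Count-table container and I/O: the interchange type every other module
# consumes. A taxon_table is an integer matrix, one row per sample, one
# column per (rank-qualified) taxon, with unique dimnames.

#' Construct a taxon count table
#'
#' A `taxon_table` holds non-negative integer read counts, one row per sample
#' and one column per taxon. Taxon labels are conventionally rank-qualified
#' ("genus:Streptococcus"), with a reserved "unclassified" bin per rank so
#' that low-confidence reads are tracked rather than dropped. All-zero taxon
#' columns are legal and preserved through I/O.
#'
#' @param counts numeric matrix of non-negative integers with unique
#'   rownames (sample ids) and colnames (taxon labels).
#' @return a `taxon_table` (integer matrix with class attribute).
#' @export
taxon_table <- function(counts) {
  counts <- as.matrix(counts)
  # an all-samples-filtered (0-row) table is legal; R drops its row names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) || is.null(colnames(counts)))
    .fail("taxon_table requires sample rownames and taxon colnames")
  if (anyDuplicated(rownames(counts)))
    .fail("duplicate sample ids: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    .fail("duplicate taxon labels: %s",
          paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    .fail("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  structure(counts, class = c("taxon_table", "matrix", "array"))
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d samples x %d taxa, %s total reads\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Per-sample read totals
#'
#' @param table a `taxon_table`.
#' @return named integer vector of row sums (the N_i of the model).
#' @export
read_totals <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  rowSums(table)
}

# strip the class so matrix ops do not dispatch back here
unclass_tt <- function(table) {
  unclass(table)[, , drop = FALSE]
}

#' Read a taxon count table from disk
#'
#' Two dialects are supported. `dense-tsv` is a tab-separated matrix with a
#' header row of taxon labels and first column `sample_id`. `biom-triplet`
#' is sparse long form with columns (sample, taxon, count); zero counts may
#' be omitted and the resulting table carries the union of observed labels.
#'
#' @param path file path.
#' @param dialect `"dense-tsv"` or `"biom-triplet"`.
#' @return a validated [taxon_table()].
#' @export
read_taxon_table <- function(path, dialect = c("dense-tsv", "biom-triplet")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .fail("file not found: %s", path)
  if (dialect == "dense-tsv") {
    df <- utils::read.delim(path, check.names = FALSE, colClasses = NA,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2 || names(df)[1] != "sample_id")
      .fail("malformed header in %s: first column must be 'sample_id'", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    bad <- which(is.na(suppressWarnings(as.numeric(m))) | as.numeric(m) < 0)
    if (length(bad))
      .fail("negative or non-numeric count at line %d of %s",
            ((bad[1] - 1) %% nrow(m)) + 2, path)
    taxon_table(m)
  } else {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("sample", "taxon", "count")
    if (!all(need %in% names(df)))
      .fail("malformed header in %s: need columns %s", path, paste(need, collapse = ", "))
    if (any(is.na(df$count)) || any(df$count < 0) || any(df$count != round(df$count))) {
      i <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))[1]
      .fail("negative or non-integer count at line %d of %s", i + 1, path)
    }
    key <- paste(df$sample, df$taxon, sep = "\r")
    if (anyDuplicated(key))
      .fail("duplicate (sample, taxon) triplet at line %d of %s",
            which(duplicated(key))[1] + 1, path)
    samples <- unique(df$sample)
    taxa <- sort(unique(df$taxon))
    m <- matrix(0L, length(samples), length(taxa), dimnames = list(samples, taxa))
    m[cbind(match(df$sample, samples), match(df$taxon, taxa))] <- as.integer(df$count)
    taxon_table(m)
  }
}

#' Write a taxon count table to disk
#'
#' Writers emit taxa in sorted label order for diffability. The triplet
#' writer omits zero counts but appends explicit zero rows for any taxon
#' that is zero in every sample, so all-zero columns round-trip.
#'
#' @inheritParams read_taxon_table
#' @param table a [taxon_table()].
#' @export
write_taxon_table <- function(table, path, dialect = c("dense-tsv", "biom-triplet")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(table, "taxon_table"))
  m <- unclass_tt(table)[, order(colnames(table)), drop = FALSE]
  if (dialect == "dense-tsv") {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(m > 0, arr.ind = TRUE)
    df <- data.frame(sample = rownames(m)[idx[, 1]],
                     taxon = colnames(m)[idx[, 2]],
                     count = m[idx], stringsAsFactors = FALSE)
    empty <- colnames(m)[colSums(m) == 0]
    if (length(empty) && nrow(m)) {
      df <- rbind(df, data.frame(sample = rownames(m)[1], taxon = empty,
                                 count = 0L, stringsAsFactors = FALSE))
    }
    df <- df[order(df$sample, df$taxon), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct and validate sample metadata
#'
#' One row per sample: subject, habitat, visit number, source project, and
#' (optionally) the number of days between that subject/habitat's two
#' visits. Drives all pairing and grouping downstream.
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `habitat`,
#'   `visit`, `project`, and optionally `interval_days`.
#' @return the validated data.frame, classed `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "subject_id", "habitat", "visit", "project")
  if (!all(need %in% names(df)))
    .fail("metadata needs columns: %s", paste(setdiff(need, names(df)), collapse = ", "))
  if (!"interval_days" %in% names(df)) df$interval_days <- NA_integer_
  if (anyDuplicated(df$sample_id)) .fail("duplicate sample_id in metadata")
  key <- paste(df$subject_id, df$habitat, df$visit, sep = "\r")
  if (anyDuplicated(key)) .fail("duplicate (subject, habitat, visit) in metadata")
  if (any(df$visit < 1)) .fail("visit must be >= 1")
  if (any(!is.na(df$interval_days) & df$interval_days < 0))
    .fail("interval_days must be non-negative")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read / write sample metadata TSV
#' @param path file path.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_metadata
#' @param metadata a [sample_metadata()] data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate per-read taxonomic assignments into a count table
#'
#' Reads classified at the requested rank with confidence at or above
#' `min_confidence` are counted under their taxon label (namespaced
#' "rank:taxon"); reads below threshold, or with no assignment at that rank,
#' fall into the reserved "rank:unclassified" bin. The threshold comparison
#' is inclusive: a read at exactly the threshold is kept. Per-sample totals
#' always equal the number of that sample's reads.
#'
#' @param assignments data.frame with columns `read_id`, `rank`, `taxon`,
#'   `confidence` (one row per read per rank).
#' @param sample_of_read named character vector mapping read_id to sample_id.
#' @param rank taxonomic rank to aggregate at (e.g. "genus").
#' @param min_confidence classifier confidence cutoff, default 0.5.
#' @return a [taxon_table()].
#' @export
aggregate_assignments <- function(assignments, sample_of_read, rank = "genus",
                                  min_confidence = 0.5) {
  stopifnot(is.data.frame(assignments),
            all(c("read_id", "rank", "taxon", "confidence") %in% names(assignments)))
  if (any(assignments$confidence < 0 | assignments$confidence > 1))
    .fail("confidence must lie in [0, 1]")
  reads <- unique(assignments$read_id)
  if (!all(reads %in% names(sample_of_read)))
    .fail("reads with no sample mapping: %s",
          paste(utils::head(setdiff(reads, names(sample_of_read)), 3), collapse = ", "))
  at_rank <- assignments[assignments$rank == rank, , drop = FALSE]
  unclass_label <- paste0(rank, ":unclassified")
  label <- rep(unclass_label, length(reads))
  names(label) <- reads
  keep <- at_rank$confidence >= min_confidence
  label[at_rank$read_id[keep]] <- paste0(rank, ":", at_rank$taxon[keep])
  sample <- sample_of_read[reads]
  samples <- unique(unname(sample))
  taxa <- sort(unique(c(label, unclass_label)))
  m <- matrix(0L, length(samples), length(taxa), dimnames = list(samples, taxa))
  tab <- table(sample, label)
  m[cbind(match(rownames(tab)[row(tab)], samples),
          match(colnames(tab)[col(tab)], taxa))] <- as.integer(tab)
  taxon_table(m)
}

#' Drop samples with too few reads
#'
#' Samples with fewer than `min_reads` reads are removed; a sample with
#' exactly `min_reads` reads survives. The taxon set is unchanged and an
#' empty result is legal. Removed ids are reported via `message()`.
#'
#' @param table a [taxon_table()].
#' @param min_reads minimum read total, default 1000.
#' @return the filtered [taxon_table()].
#' @export
filter_min_reads <- function(table, min_reads = 1000) {
  stopifnot(inherits(table, "taxon_table"), min_reads >= 1)
  keep <- read_totals(table) >= min_reads
  if (any(!keep))
    message(sprintf("filter_min_reads: removed %d sample(s): %s", sum(!keep),
                    paste(rownames(table)[!keep], collapse = ", ")))
  taxon_table(unclass_tt(table)[keep, , drop = FALSE])
}
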