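# Small in-code fixtures shared across test files.

# a 2x2 table with counts [[3,0],[1,2]]
tiny_table <- function() {
  taxon_table(matrix(c(3L, 0L, 1L, 2L), 2, 2, byrow = TRUE,
                     dimnames = list(c("sA", "sB"),
                                     c("genus:Alpha", "genus:Beta"))))
}

# n samples of equal depth from one DM habitat, with metadata for habitat h
dm_habitat <- function(pi, theta, n, depth, seed, habitat = "hab",
                       prefix = habitat) {
  tt <- sample_dm(pi, theta, n, depth, seed, prefix = paste0(prefix, "."))
  md <- sample_metadata(data.frame(
    sample_id = rownames(tt),
    subject_id = sprintf("subj%03d", seq_len(n)),
    habitat = habitat, visit = 1L, project = "test",
    stringsAsFactors = FALSE))
  list(table = tt, metadata = md)
}

# all permutations of 1..n (for exhaustive accumulation-curve oracles)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (i in 0:(n - 1)) out[[length(out) + 1]] <- append(p, n, after = i)
  }
  out
}
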