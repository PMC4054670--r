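test_that("shared prevalent sets report both overlap denominators", {
  m <- matrix(c(10L, 5L, 0L, 8L, 7L, 0L, 9L, 0L, 1L), 3, 3, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:3), c("a", "b", "c")))
  tt <- taxon_table(m)
  same <- shared_prevalent_genera(tt, tt)
  expect_equal(same$jaccard, 1)
  expect_equal(same$frac_of_a, 1)

  other <- taxon_table(matrix(c(0L, 10L, 0L, 12L), 2, 2, byrow = TRUE,
                              dimnames = list(c("x1", "x2"), c("a", "z"))))
  dis <- shared_prevalent_genera(tt, other)
  expect_setequal(dis$prevalent_a, c("a", "b"))
  expect_equal(dis$prevalent_b, "z")
  expect_equal(dis$jaccard, 0)

  # two cohorts from one DM population share nearly all prevalent taxa
  pi <- geometric_pi(12, 0.7)
  ca <- sample_dm(pi, 0.1, 100, 1000, seed = 501, prefix = "ca")
  cb <- sample_dm(pi, 0.1, 100, 1000, seed = 502, prefix = "cb")
  res <- shared_prevalent_genera(ca, cb)
  expect_gt(res$jaccard, 0.85)
})

test_that("taxon_shift_test matches exhaustive enumeration at n = 3 vs 3", {
  ma <- taxon_table(matrix(c(10L, 90L, 20L, 80L, 30L, 70L), 3, 2, byrow = TRUE,
                           dimnames = list(c("a1", "a2", "a3"), c("t", "o"))))
  mb <- taxon_table(matrix(c(40L, 60L, 50L, 50L, 60L, 40L), 3, 2, byrow = TRUE,
                           dimnames = list(c("b1", "b2", "b3"), c("t", "o"))))
  res <- taxon_shift_test(ma, mb, "t")

  # oracle: enumerate all C(6,3) group assignments of the pooled values
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  obs_w <- sum(rank(vals)[1:3]) - 3 * 4 / 2
  combos <- combn(6, 3)
  ws <- apply(combos, 2, function(idx) sum(rank(vals)[idx]) - 6)
  p_exact <- mean(abs(ws - 4.5) >= abs(obs_w - 4.5))
  expect_equal(res$p, p_exact, tolerance = 1e-12)

  # fully tied data
  tied <- taxon_table(matrix(c(50L, 50L, 50L, 50L), 2, 2, byrow = TRUE,
                             dimnames = list(c("x", "y"), c("t", "o"))))
  expect_equal(taxon_shift_test(tied, tied, "t")$p, 1)
  expect_error(taxon_shift_test(ma, mb, "nope"), "absent")
})

test_that("taxon_shift_test has power against a constructed shift", {
  pi_a <- c(0.3, 0.7); pi_b <- c(0.5, 0.5)
  rej <- mean(vapply(1:40, function(r) {
    ta <- sample_dm(pi_a, 0.05, 50, 500, seed = derive_seed(600, "a", r), prefix = "a")
    tb <- sample_dm(pi_b, 0.05, 50, 500, seed = derive_seed(600, "b", r), prefix = "b")
    taxon_shift_test(ta, tb, "genus:tax001")$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.8)
})

test_that("rank-sum p is invariant under monotone transforms of abundance", {
  set.seed(71)
  ma <- sample_dm(c(0.4, 0.6), 0.1, 12, 400, seed = 1, prefix = "a")
  mb <- sample_dm(c(0.6, 0.4), 0.1, 12, 400, seed = 2, prefix = "b")
  p1 <- taxon_shift_test(ma, mb, "genus:tax001")$p
  # squaring counts (strictly monotone at equal depth) preserves all ranks
  sq <- function(tt) taxon_table(matrix(as.integer(unclass(tt))^2L,
                                        nrow(tt), 2, dimnames = dimnames(tt)))
  p2 <- suppressWarnings(taxon_shift_test(sq(ma), sq(mb), "genus:tax001")$p)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("complete-linkage clustering matches a manual trace and scores purity", {
  # 4 samples with a hand-computable Bray-Curtis matrix:
  # p=(10,0), q=(9,1), r=(1,9), s=(0,10): d(p,q)=0.1, d(r,s)=0.1,
  # d(p,r)=0.9, d(p,s)=1, d(q,r)=0.8, d(q,s)=0.9
  m <- matrix(c(10L, 0L, 9L, 1L, 1L, 9L, 0L, 10L), 4, 2, byrow = TRUE,
              dimnames = list(c("p", "q", "r", "s"), c("a", "b")))
  tt <- taxon_table(m)
  lab <- c(p = "left", q = "left", r = "right", s = "right")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  cl <- cluster_samples(tt, lab, k = 2, newick_path = nwk)
  # manual trace: merge {p,q} at 0.1, {r,s} at 0.1, then all at max = 1
  expect_equal(sort(cl$hclust$height), c(0.1, 0.1, 1))
  expect_equal(cl$purity, 1)
  expect_equal(unname(cl$clusters[c("p", "q", "r", "s")]), c(1, 1, 2, 2))
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(m))

  # input order invariance (up to relabeling)
  cl2 <- cluster_samples(taxon_table(m[c(3, 1, 4, 2), ]), lab, k = 2)
  expect_equal(cl2$purity, 1)
  expect_equal(sort(cl2$hclust$height), sort(cl$hclust$height))
})

test_that("project-separated cohorts cluster pure; arbitrary splits do not", {
  pi_a <- geometric_pi(10, 0.8)
  pi_b <- rev(pi_a)
  ta <- sample_dm(pi_a, 0.05, 15, 1000, seed = 801, prefix = "projA")
  tb <- sample_dm(pi_b, 0.05, 15, 1000, seed = 802, prefix = "projB")
  tt <- taxon_table(rbind(unclass(ta), unclass(tb)))
  lab <- setNames(rep(c("A", "B"), each = 15), rownames(tt))
  expect_equal(cluster_samples(tt, lab, k = 2)$purity, 1)

  # one cohort split at random into pseudo-cohorts: purity near baseline
  pseudo <- setNames(rep(c("x", "y"), length.out = 15), rownames(ta))
  pur <- cluster_samples(ta, pseudo, k = 2)$purity
  expect_lt(pur, 0.9)
})

test_that("a project batch effect dominates a phenotype label in clustering", {
  pi <- geometric_pi(12, 0.75)
  bias <- c(rep(3, 4), rep(1, 8)) # project B inflates the first 4 taxa
  pi_b <- pi * bias / sum(pi * bias)
  n <- 16
  ta <- sample_dm(pi, 0.05, n, 1000, seed = 901, prefix = "pa")
  tb <- sample_dm(pi_b, 0.05, n, 1000, seed = 902, prefix = "pb")
  tt <- taxon_table(rbind(unclass(ta), unclass(tb)))
  project <- setNames(rep(c("A", "B"), each = n), rownames(tt))
  # phenotype assigned within project, independent of composition
  phenotype <- setNames(rep(c("healthy", "case"), length.out = 2 * n), rownames(tt))
  pur_project <- cluster_samples(tt, project, k = 2)$purity
  pur_phenotype <- cluster_samples(tt, phenotype, k = 2)$purity
  expect_gt(pur_project, pur_phenotype)
})
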