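test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  m <- matrix(c(6L, 2L, 2L, 6L, 8L, 0L, 0L, 8L), 4, 2, byrow = TRUE,
              dimnames = list(c("p", "q", "r", "s"), c("a", "b")))
  d <- bray_curtis(taxon_table(m))
  expect_equal(d["p", "q"], 1 - 2 * (2 + 2) / 16) # 0.5 by hand
  expect_equal(d["p", "p"], 0)
  expect_equal(d["r", "s"], 1) # disjoint support
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("Mantel self-comparison, affine invariance, and vegan agreement", {
  set.seed(101)
  m <- matrix(rpois(6 * 5, 20) + 1L, 6, 5,
              dimnames = list(sprintf("s%d", 1:6), sprintf("t%d", 1:5)))
  dA <- bray_curtis(taxon_table(m))
  res <- mantel_test(dA, dA, n_permutations = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)

  dB <- 0.2 + 0.5 * dA; diag(dB) <- 0
  expect_equal(mantel_test(dA, dB, n_permutations = 19, seed = 1)$r, 1)

  # independent cross-check of the statistic against vegan
  m2 <- matrix(rpois(6 * 5, 15) + 1L, 6, 5, dimnames = dimnames(m))
  dC <- bray_curtis(taxon_table(m2))
  v <- vegan::mantel(as.dist(dA), as.dist(dC), permutations = 0)
  expect_equal(mantel_test(dA, dC, n_permutations = 9, seed = 1)$r,
               unname(v$statistic), tolerance = 1e-12)

  dBad <- dC; rownames(dBad) <- colnames(dBad) <- letters[1:6]
  expect_error(mantel_test(dA, dBad), "different samples")
  expect_error(mantel_test(dA[1:3, 1:3], dA[1:3, 1:3]), ">= 4")
})

test_that("Mantel p-values are calibrated under the null", {
  # p should be (near) uniform on its attainable grid for independent matrices
  ps <- vapply(1:60, function(r) {
    ta <- sample_dm(geometric_pi(6, 0.7), 0.2, 8, 300,
                    seed = derive_seed(300, "a", r), prefix = "x")
    tb <- sample_dm(geometric_pi(6, 0.7), 0.2, 8, 300,
                    seed = derive_seed(300, "b", r), prefix = "x")
    mantel_test(bray_curtis(ta), bray_curtis(tb),
                n_permutations = 49, seed = r)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("habitat_association: self-pairing is exact, independence is null", {
  hab <- dm_habitat(geometric_pi(15, 0.75), 0.15, 24, 1500, seed = 201,
                    habitat = "A")
  self <- habitat_association(hab$table, hab$table, hab$metadata, seed = 5,
                              n_permutations = 99)
  expect_equal(self$spearman_richness, 1)
  expect_equal(self$mantel_r, 1)
  expect_equal(self$n_shared_subjects, 24)

  habB <- dm_habitat(geometric_pi(15, 0.75), 0.15, 24, 1500, seed = 202,
                     habitat = "B", prefix = "B")
  md <- sample_metadata(rbind(hab$metadata, habB$metadata))
  cross <- habitat_association(hab$table, habB$table, md, seed = 5,
                               n_permutations = 99)
  expect_lt(abs(cross$spearman_richness), 3 / sqrt(23)) # ~3 SE of zero
  expect_true(cross$defined)

  # under 3 shared subjects: flagged undefined
  few <- dm_habitat(geometric_pi(15, 0.75), 0.15, 2, 1500, seed = 203,
                    habitat = "C", prefix = "C")
  md2 <- sample_metadata(rbind(hab$metadata[1:2, ], few$metadata))
  und <- habitat_association(taxon_table(unclass(hab$table)[1:2, ]),
                             few$table, md2)
  expect_false(und$defined)
  expect_true(is.na(und$spearman_richness))
})

test_that("coupled subject-level richness drivers give positive correlation", {
  # couple richness across two habitats: subject i carries only the first
  # 5 + i taxa in both habitats
  n <- 20; K <- 30
  mk <- function(habitat, seed) {
    m <- matrix(0L, n, K,
                dimnames = list(sprintf("%s.s%02d", habitat, 1:n),
                                sprintf("genus:t%02d", 1:K)))
    set.seed(seed)
    for (i in 1:n) {
      k_i <- 5 + i
      m[i, 1:k_i] <- as.integer(rmultinom(1, 2000, rep(1 / k_i, k_i)))
    }
    list(table = taxon_table(m),
         metadata = sample_metadata(data.frame(
           sample_id = rownames(m), subject_id = sprintf("subj%02d", 1:n),
           habitat = habitat, visit = 1L, project = "t",
           stringsAsFactors = FALSE)))
  }
  A <- mk("A", 1); B <- mk("B", 2)
  md <- sample_metadata(rbind(A$metadata, B$metadata))
  res <- habitat_association(A$table, B$table, md, seed = 9, n_permutations = 49)
  expect_gt(res$spearman_richness, 0.5)
})

test_that("temporal stability separates stable from labile habitats", {
  # identical visits at full depth: rho exactly 1
  n <- 6
  m <- matrix(rep(c(500L, 300L, 150L, 50L), n), n, 4, byrow = TRUE,
              dimnames = list(c(sprintf("v1.s%d", 1:3), sprintf("v2.s%d", 1:3)),
                              sprintf("genus:t%d", 1:4)))
  md <- sample_metadata(data.frame(
    sample_id = rownames(m), subject_id = rep(sprintf("s%d", 1:3), 2),
    habitat = "h", visit = rep(1:2, each = 3), project = "t",
    interval_days = 100L, stringsAsFactors = FALSE))
  st <- temporal_stability(taxon_table(m), md, "h", depth = 1000, seed = 1)
  expect_equal(st$spearman, rep(1, 3))

  # a permuted visit 2 decorrelates
  m2 <- m
  set.seed(5)
  for (i in 4:6) m2[i, ] <- m2[i, c(3, 4, 2, 1)]
  st2 <- temporal_stability(taxon_table(m2), md, "h", depth = 1000, seed = 1)
  expect_lt(mean(st2$spearman), mean(st$spearman))

  # subjects missing a visit are skipped with a message
  md3 <- md[-4, ]
  expect_message(st3 <- temporal_stability(taxon_table(m[-4, ]),
                                           sample_metadata(md3), "h",
                                           depth = 1000, seed = 1),
                 "skipped")
  expect_equal(nrow(st3), 2)
})

test_that("interval_vs_stability flags degenerate inputs and recovers decay", {
  s_const <- data.frame(subject_id = c("a", "b", "c"),
                        spearman = c(0.9, 0.5, 0.7), interval_days = c(100L, 100L, 100L))
  expect_false(interval_vs_stability(s_const)$defined)

  set.seed(77)
  iv <- sample(30:359, 40)
  s_decay <- data.frame(subject_id = sprintf("s%d", 1:40),
                        spearman = 1 - iv / 400 + rnorm(40, 0, 0.02),
                        interval_days = iv)
  res <- interval_vs_stability(s_decay)
  expect_true(res$defined)
  expect_lt(res$rho, -0.8)

  s_ind <- data.frame(subject_id = sprintf("s%d", 1:40),
                      spearman = rnorm(40, 0.7, 0.1), interval_days = iv)
  expect_lt(abs(interval_vs_stability(s_ind)$rho), 3 / sqrt(39))
})

test_that("dominant-taxon tracking: home habitat correlates with itself at 1", {
  hab <- dm_habitat(geometric_pi(10, 0.5), 0.2, 15, 1000, seed = 401,
                    habitat = "home")
  other <- dm_habitat(geometric_pi(10, 0.5), 0.2, 15, 1000, seed = 402,
                      habitat = "away", prefix = "away")
  md <- sample_metadata(rbind(hab$metadata, other$metadata))
  tables <- list(home = hab$table, away = other$table)
  taxon <- colnames(hab$table)[1]
  res <- dominant_taxon_cross_correlation(taxon, "home", tables, md)
  expect_equal(res$spearman[res$habitat == "home"], 1)
  expect_lt(abs(res$spearman[res$habitat == "away"]), 3 / sqrt(14))
  expect_error(dominant_taxon_cross_correlation("genus:absent", "home", tables, md),
               "not present")
})
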