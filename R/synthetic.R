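# Habitat-structured synthetic count tables drawn from the
# Dirichlet-multinomial model. The generator exists so that every
# downstream stage (rarefaction, diversity, theta estimation, temporal
# stability, cohort comparison) can be exercised against known ground
# truth, without the original sequence archives.

#' Describe one synthetic habitat
#'
#' A scenario fixes the habitat-level mean composition `pi`, the
#' between-subject overdispersion `theta`, the cohort size, the per-sample
#' sequencing-depth distribution, and a `stability` weight in [0, 1]
#' controlling how much of a subject's visit-1 latent composition is reused
#' at visit 2 (1 = identical latent community, 0 = a fresh draw).
#'
#' @param habitat habitat name (unique within a suite).
#' @param pi probability vector over taxa (sums to 1).
#' @param theta overdispersion in [0, 1).
#' @param n_subjects number of subjects.
#' @param depth either a single fixed read depth, or a list
#'   `list(meanlog=, sdlog=, min=)` for a lognormal depth truncated below.
#' @param stability visit-2 latent-composition reuse weight in [0, 1].
#' @param taxa optional taxon labels (default "genus:tax001", ...).
#' @return a `habitat_scenario` list.
#' @export
habitat_scenario <- function(habitat, pi, theta, n_subjects,
                             depth = 1000, stability = 1, taxa = NULL) {
  if (abs(sum(pi) - 1) > 1e-9) .fail("pi must sum to 1 (got %.12f)", sum(pi))
  if (any(pi < 0)) .fail("pi must be non-negative")
  if (theta < 0 || theta >= 1) .fail("theta must lie in [0, 1)")
  if (stability < 0 || stability > 1) .fail("stability must lie in [0, 1]")
  if (is.null(taxa))
    taxa <- sprintf("genus:tax%03d", seq_along(pi))
  stopifnot(length(taxa) == length(pi))
  structure(list(habitat = habitat, pi = pi, theta = theta,
                 n_subjects = as.integer(n_subjects), depth = depth,
                 stability = stability, taxa = taxa),
            class = "habitat_scenario")
}

# Draw one latent composition: Dirichlet(pi * (1-theta)/theta), or the
# point mass at pi when theta == 0. Zero pi entries stay exactly zero.
draw_latent <- function(pi, theta) {
  if (theta == 0) return(pi)
  a <- pi * (1 - theta) / theta
  g <- numeric(length(pi))
  pos <- a > 0
  g[pos] <- stats::rgamma(sum(pos), shape = a[pos], rate = 1)
  s <- sum(g)
  if (s == 0) { # pathological underflow; fall back to the mean
    return(pi)
  }
  g / s
}

draw_depth <- function(depth_spec) {
  if (is.list(depth_spec)) {
    d <- 0
    while (d < depth_spec$min)
      d <- round(stats::rlnorm(1, depth_spec$meanlog, depth_spec$sdlog))
    as.integer(d)
  } else as.integer(depth_spec)
}

#' Simulate a Dirichlet-multinomial cohort
#'
#' For each subject a latent taxon-frequency vector is drawn from a
#' Dirichlet with concentration `pi * (1 - theta) / theta`, then read
#' counts are drawn multinomially at the given depth; at `theta = 0` the
#' draw is multinomial from `pi` directly (no between-subject variation
#' beyond sampling). Each subject has its own RNG stream derived from
#' `(seed, subject index)`, so enlarging the cohort never changes existing
#' subjects' draws.
#'
#' @param pi probability vector (sums to 1).
#' @param theta overdispersion in [0, 1); `theta = 1` is rejected (the
#'   degenerate one-taxon-per-subject limit).
#' @param n_subjects number of subjects.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @param taxa optional taxon labels.
#' @param prefix sample-id prefix.
#' @return a [taxon_table()] with one row per subject.
#' @export
sample_dm <- function(pi, theta, n_subjects, depth, seed, taxa = NULL,
                      prefix = "s") {
  if (theta < 0 || theta >= 1) .fail("theta must lie in [0, 1)")
  stopifnot(depth >= 1, abs(sum(pi) - 1) < 1e-9)
  k <- length(pi)
  if (is.null(taxa)) taxa <- sprintf("genus:tax%03d", seq_len(k))
  m <- matrix(0L, n_subjects, k,
              dimnames = list(sprintf("%s%04d", prefix, seq_len(n_subjects)), taxa))
  for (i in seq_len(n_subjects)) {
    m[i, ] <- with_seed(derive_seed(seed, "subj", i), {
      p <- draw_latent(pi, theta)
      as.integer(stats::rmultinom(1, depth, p))
    })
  }
  taxon_table(m)
}

#' Generate a multi-habitat, multi-visit synthetic study
#'
#' One sample per subject x habitat x visit. Visit-2 latent compositions
#' are a `stability`-weighted mixture of the subject's visit-1 latent draw
#' and a fresh Dirichlet draw, giving habitat-dependent temporal stability.
#' Metadata carries subject, habitat, visit, project, and a per-subject
#' `interval_days` drawn uniformly from 30..359 days.
#'
#' @param scenarios list of [habitat_scenario()] objects (unique habitats).
#' @param n_visits 1 or 2.
#' @param seed integer seed.
#' @param project project label stored in the metadata.
#' @return list with elements `table` (a [taxon_table()] over the union
#'   taxon set) and `metadata` (a [sample_metadata()]).
#' @export
make_scenario_suite <- function(scenarios, n_visits = 2, seed = 1,
                                project = "synthetic") {
  stopifnot(n_visits %in% 1:2)
  habs <- vapply(scenarios, `[[`, "", "habitat")
  if (anyDuplicated(habs)) .fail("duplicate habitat names")
  all_taxa <- sort(unique(unlist(lapply(scenarios, `[[`, "taxa"))))
  rows <- list(); meta <- list()
  for (sc in scenarios) {
    for (i in seq_len(sc$n_subjects)) {
      subj <- sprintf("subj%03d", i)
      sseed <- derive_seed(seed, sc$habitat, "subj", i)
      draws <- with_seed(sseed, {
        lat1 <- draw_latent(sc$pi, sc$theta)
        lat2 <- sc$stability * lat1 +
          (1 - sc$stability) * draw_latent(sc$pi, sc$theta)
        d1 <- draw_depth(sc$depth); d2 <- draw_depth(sc$depth)
        iv <- sample(30:359, 1)
        list(v1 = as.integer(stats::rmultinom(1, d1, lat1)),
             v2 = as.integer(stats::rmultinom(1, d2, lat2)),
             interval = iv)
      })
      for (v in seq_len(n_visits)) {
        id <- sprintf("%s.%s.v%d", sc$habitat, subj, v)
        cnt <- if (v == 1) draws$v1 else draws$v2
        full <- integer(length(all_taxa))
        names(full) <- all_taxa
        full[sc$taxa] <- cnt
        rows[[id]] <- full
        meta[[id]] <- data.frame(sample_id = id, subject_id = subj,
                                 habitat = sc$habitat, visit = v,
                                 project = project,
                                 interval_days = draws$interval,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  list(table = taxon_table(m),
       metadata = sample_metadata(do.call(rbind, c(meta, make.row.names = FALSE))))
}

#' Geometric-series mean composition
#'
#' Builds a mean taxon-frequency vector proportional to `ratio^(0:(K-1))`,
#' optionally with an explicit dominant first taxon: with `dominant = d`,
#' taxon 1 takes mass `d` and the geometric series is renormalised over the
#' remaining `K - 1` taxa to mass `1 - d`.
#'
#' @param K number of taxa.
#' @param ratio geometric decay ratio in (0, 1); closer to 1 is more even.
#' @param dominant optional mass of the first taxon.
#' @return probability vector of length `K`.
#' @export
geometric_pi <- function(K, ratio, dominant = NULL) {
  stopifnot(K >= 1, ratio > 0, ratio < 1)
  if (is.null(dominant)) {
    w <- ratio^(0:(K - 1))
    w / sum(w)
  } else {
    stopifnot(dominant > 0, dominant < 1, K >= 2)
    w <- ratio^(0:(K - 2))
    c(dominant, (1 - dominant) * w / sum(w))
  }
}

#' The default four-habitat synthetic suite
#'
#' A compact emulation of the qualitative habitat structure of the human
#' microbiome: an even, stable "oral-like" habitat with low overdispersion
#' (theta = 0.05); a "stool-like" habitat with one dominant taxon and low
#' overdispersion (theta = 0.08); a long-tailed, environmentally exposed
#' "skin-like" habitat with high overdispersion (theta = 0.3) and low
#' temporal stability; and a "vaginal-like" habitat with a single
#' hyper-dominant taxon, the highest overdispersion (theta = 0.4), and low
#' stability. All habitats draw from one shared pool of 60 genera — as in
#' real body habitats, where the same genera recur with different dominance
#' orders — with each habitat's geometric abundance ranking rotated to a
#' different part of the pool, so every genus has positive mean frequency
#' everywhere but a different dominant genus heads each habitat. Each
#' habitat has 100 subjects sampled at two visits with lognormal depths
#' truncated at 1,200 reads.
#'
#' @param seed integer seed.
#' @param n_subjects subjects per habitat, default 100.
#' @return as [make_scenario_suite()]: list(table, metadata).
#' @export
default_habitat_suite <- function(seed = 1, n_subjects = 100) {
  depth <- list(meanlog = log(3000), sdlog = 0.4, min = 1200)
  taxa <- sprintf("genus:tax%03d", 1:60)
  rotate <- function(pi, by) pi[((seq_along(pi) - 1 - by) %% length(pi)) + 1]
  scen <- list(
    habitat_scenario("oral-like",
                     geometric_pi(60, 0.93), theta = 0.05,
                     n_subjects = n_subjects, depth = depth, stability = 0.9,
                     taxa = taxa),
    habitat_scenario("stool-like",
                     rotate(geometric_pi(60, 0.80, dominant = 0.45), 15),
                     theta = 0.08,
                     n_subjects = n_subjects, depth = depth, stability = 0.9,
                     taxa = taxa),
    habitat_scenario("skin-like",
                     rotate(geometric_pi(60, 0.60), 30), theta = 0.30,
                     n_subjects = n_subjects, depth = depth, stability = 0.3,
                     taxa = taxa),
    habitat_scenario("vaginal-like",
                     rotate(geometric_pi(60, 0.50, dominant = 0.90), 45),
                     theta = 0.40,
                     n_subjects = n_subjects, depth = depth, stability = 0.4,
                     taxa = taxa)
  )
  make_scenario_suite(scen, n_visits = 2, seed = seed)
}

#' Read a scenario-suite config file
#'
#' YAML with one stanza per habitat: `habitat`, `K`, `theta`, `ratio` (and
#' optional `dominant`) for the geometric mean composition, `n_subjects`,
#' `depth` (integer, or mapping with meanlog/sdlog/min), `stability`.
#'
#' @param path YAML file path.
#' @return list of [habitat_scenario()] objects.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg$habitats, function(h) {
    pi <- geometric_pi(h$K, h$ratio, h$dominant)
    habitat_scenario(h$habitat, pi, h$theta, h$n_subjects,
                     depth = if (is.list(h$depth)) h$depth else as.integer(h$depth),
                     stability = if (is.null(h$stability)) 1 else h$stability)
  })
}
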