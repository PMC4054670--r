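# End-to-end orchestration: filter -> rarefy -> enabled analysis stages,
# all artifacts written as TSV with a manifest recording the config digest
# and seeds, so a rerun with the same config is byte-identical.

#' Validate a pipeline configuration
#'
#' A config is a list (or YAML file) with entries: either `table` +
#' `metadata` paths or `scenario` ("default" or a scenario YAML path);
#' `depth` (rarefaction depth, default 1000), `min_reads` (sample filter,
#' default 1000, must be >= depth), `seed`, `out_dir`, and `stages`, a
#' character subset of c("diversity", "dm", "association", "biogeography",
#' "cohort_compare").
#'
#' @param config list or path to a YAML file.
#' @return the validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(depth = 1000, min_reads = 1000, seed = 1,
                   stages = c("diversity", "dm", "association",
                              "biogeography", "cohort_compare"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$out_dir)) .fail("config needs out_dir")
  if (config$depth > config$min_reads)
    .fail("depth (%d) must not exceed min_reads (%d)", config$depth, config$min_reads)
  has_files <- !is.null(config$table) && !is.null(config$metadata)
  if (!has_files && is.null(config$scenario))
    .fail("config needs either table+metadata paths or a scenario")
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Loads (or generates) the count table and metadata, removes samples
#' below `min_reads`, rarefies to `depth`, and runs the enabled stages,
#' writing each artifact as TSV under `out_dir`. Stage seeds are derived
#' from the master seed and the stage name, so disabling one stage never
#' changes another's randomness.
#'
#' @param config list or YAML path; see [pipeline_config()].
#' @return invisible manifest data.frame (artifact name, path).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$table)) {
    tab <- read_taxon_table(cfg$table, dialect = "dense-tsv")
    md <- read_sample_metadata(cfg$metadata)
  } else if (identical(cfg$scenario, "default")) {
    suite <- default_habitat_suite(seed = derive_seed(cfg$seed, "generate"))
    tab <- suite$table; md <- suite$metadata
  } else {
    scen <- read_scenario_config(cfg$scenario)
    suite <- make_scenario_suite(scen, seed = derive_seed(cfg$seed, "generate"))
    tab <- suite$table; md <- suite$metadata
  }
  artifacts <- list()
  emit <- function(name, path) artifacts[[name]] <<- path

  tab <- filter_min_reads(tab, cfg$min_reads)
  md <- sample_metadata(md[md$sample_id %in% rownames(tab), , drop = FALSE])
  rt <- rarefy_table(tab, depth = cfg$depth, seed = derive_seed(cfg$seed, "rarefy"))
  emit("rarefied_table", write_taxon_table(rt, file.path(cfg$out_dir, "rarefied.tsv")))
  emit("metadata", write_sample_metadata(md, file.path(cfg$out_dir, "metadata.tsv")))

  habitats <- sort(unique(md$habitat))
  hab_tab <- function(h, visit = 1) {
    ids <- md$sample_id[md$habitat == h & md$visit == visit]
    taxon_table(unclass_tt(rt)[ids, , drop = FALSE])
  }

  if ("diversity" %in% cfg$stages) {
    ds <- diversity_summary(rt, md)
    emit("diversity", write_tsv(ds, file.path(cfg$out_dir, "diversity.tsv")))
    if (length(habitats) >= 2) {
      pt <- pairwise_group_tests(ds$shannon, ds$habitat)
      emit("shannon_pairwise",
           write_tsv(data.frame(habitat = rownames(pt$p_adjusted),
                                pt$p_adjusted, check.names = FALSE),
                     file.path(cfg$out_dir, "shannon_pairwise_p.tsv")))
    }
    rac <- do.call(rbind, lapply(habitats, function(h)
      cbind(habitat = h, rank_abundance_curve(hab_tab(h)))))
    emit("rank_abundance", write_tsv(rac, file.path(cfg$out_dir, "rank_abundance.tsv")))
    acc <- do.call(rbind, lapply(habitats, function(h) {
      a <- accumulation_curve(hab_tab(h), seed = derive_seed(cfg$seed, "accum", h))
      data.frame(habitat = h, n_samples = a$n_samples_axis,
                 mean_richness = a$mean_richness, sd_richness = a$sd_richness)
    }))
    emit("accumulation", write_tsv(acc, file.path(cfg$out_dir, "accumulation.tsv")))
  }

  if ("dm" %in% cfg$stages) {
    dm <- do.call(rbind, lapply(habitats, function(h) {
      fit <- fit_mle(hab_tab(h), n_boot = 50, seed = derive_seed(cfg$seed, "dm", h))
      data.frame(habitat = h, theta = fit$params$theta, theta_se = fit$theta_se,
                 log_likelihood = fit$log_likelihood, n_subjects = fit$n_subjects)
    }))
    emit("dm_fits", write_tsv(dm, file.path(cfg$out_dir, "dm_fits.tsv")))
  }

  if ("association" %in% cfg$stages && length(habitats) >= 2) {
    assoc <- do.call(rbind, lapply(utils::combn(habitats, 2, simplify = FALSE),
      function(hp) {
        ha <- habitat_association(hab_tab(hp[1]), hab_tab(hp[2]), md,
                                  seed = derive_seed(cfg$seed, "assoc", hp[1], hp[2]),
                                  n_permutations = 199)
        data.frame(habitat_a = hp[1], habitat_b = hp[2],
                   n_shared = ha$n_shared_subjects,
                   spearman_richness = ha$spearman_richness,
                   mantel_r = ha$mantel_r, mantel_p = ha$mantel_p)
      }))
    emit("association", write_tsv(assoc, file.path(cfg$out_dir, "association.tsv")))
    stab <- do.call(rbind, lapply(habitats, function(h) {
      ids <- md$sample_id[md$habitat == h]
      s <- temporal_stability(taxon_table(unclass_tt(tab)[ids, , drop = FALSE]),
                              md, h, depth = cfg$depth,
                              seed = derive_seed(cfg$seed, "stability", h))
      if (nrow(s)) cbind(habitat = h, s) else NULL
    }))
    if (!is.null(stab))
      emit("stability", write_tsv(stab, file.path(cfg$out_dir, "stability.tsv")))
  }

  if ("biogeography" %in% cfg$stages) {
    pa <- do.call(rbind, lapply(habitats, function(h)
      cbind(habitat = h, prevalence_abundance(hab_tab(h)))))
    emit("prevalence_abundance",
         write_tsv(pa, file.path(cfg$out_dir, "prevalence_abundance.tsv")))
    tq <- do.call(rbind, lapply(habitats, function(h)
      cbind(habitat = h, taxon_quantiles(hab_tab(h)))))
    emit("taxon_quantiles", write_tsv(tq, file.path(cfg$out_dir, "taxon_quantiles.tsv")))
    census <- shared_taxa_census(stats::setNames(lapply(habitats, hab_tab), habitats))
    emit("shared_taxa",
         write_tsv(data.frame(taxon = rownames(census$membership),
                              n_habitats = census$n_habitats,
                              census$membership, check.names = FALSE),
                   file.path(cfg$out_dir, "shared_taxa.tsv")))
  }

  if ("cohort_compare" %in% cfg$stages && length(unique(md$project)) >= 2) {
    projects <- sort(unique(md$project))
    lab <- stats::setNames(md$project, md$sample_id)
    cl <- cluster_samples(rt, lab, k = length(projects),
                          newick_path = file.path(cfg$out_dir, "cluster.nwk"))
    emit("cluster_newick", file.path(cfg$out_dir, "cluster.nwk"))
    emit("cluster_purity",
         write_tsv(data.frame(k = length(projects), purity = cl$purity),
                   file.path(cfg$out_dir, "cluster_purity.tsv")))
  }

  manifest <- data.frame(artifact = names(artifacts),
                         path = unlist(artifacts, use.names = FALSE),
                         stringsAsFactors = FALSE)
  manifest$seed <- cfg$seed
  manifest$depth <- cfg$depth
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(manifest)
}
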