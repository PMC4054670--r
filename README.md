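# dmbiogeo

Quantifying how much human-associated microbial communities differ between
subjects, across body habitats, and over time — from genus-level 16S rRNA
count tables.

A habitat's samples carry two layers of randomness: multinomial read
sampling within a subject, and real compositional differences between
subjects. `dmbiogeo` separates them with the **Dirichlet-multinomial (DM)
model**: subject *i*'s counts $x_i$ over $K$ genera at depth $N_i$ follow

$$P(X_i = x_i) = \frac{N_i!}{x_{i1}!\cdots x_{iK}!}
  \frac{\prod_{j}\prod_{r=1}^{x_{ij}} [\pi_j(1-\theta) + (r-1)\theta]}
       {\prod_{r=1}^{N_i} [(1-\theta) + (r-1)\theta]}$$

where $\pi$ is the habitat's mean genus-frequency vector and
$\theta \in [0,1)$ the **overdispersion**: $\theta = 0$ is the multinomial
(all subjects share $\pi$); larger $\theta$ means larger between-subject
variation, via
$\mathrm{Var}(x_{ij}/N_i) = \pi_j(1-\pi_j)\,[1 + (N_i-1)\theta]/N_i$.
Stable habitats (oral sites, stool) sit below $\theta \approx 0.1$;
dominated, volatile habitats (vaginal, skin) reach 0.3–0.4.

Around the model, the package implements the full habitat-characterisation
pipeline:

* **tables_io** — dense-TSV / sparse-triplet count tables, sample metadata,
  aggregation of per-read classifier assignments (confidence ≥ 0.5 kept,
  the rest binned "unclassified"), the <1,000-read sample filter;
* **rarefaction** — without-replacement subsampling to a common depth
  (multivariate hypergeometric), relative abundances;
* **diversity** — richness, Shannon (natural log), Welch t-tests with
  Bonferroni correction across habitat pairs, accumulation curves,
  rank-abundance curves;
* **dm_model** — `dm_log_pmf()`, `fit_moments()`, `fit_mle()` with
  bootstrap SEs, and `theta_across_depths()` (depth invariance of θ);
* **association** — Spearman correlation of paired-habitat richness,
  Mantel tests on Bray-Curtis matrices, two-visit temporal stability,
  dominant-taxon tracking across habitats;
* **biogeography** — prevalence vs carrier abundance (cosmopolitan vs
  endemic genera), prevalence as a function of depth, shared-taxon census,
  abundance quantiles;
* **cohort_compare** — shared prevalent genera, Wilcoxon rank-sum shifts,
  complete-linkage Bray-Curtis clustering with cohort purity;
* **synthetic_data** — a DM generator of habitat-structured, two-visit,
  multi-cohort studies, used throughout the tests as ground truth.

## Worked example

Generate the default four-habitat synthetic study (100 subjects per
habitat, two visits), standardise depth, and compare habitats:

```r
library(dmbiogeo)

suite <- default_habitat_suite(seed = 1)
suite$table
#> taxon_table: 800 samples x 60 taxa, 2,636,061 total reads

tab <- filter_min_reads(suite$table, 1000)
rt  <- rarefy_table(tab, depth = 1000, seed = 1)
md  <- suite$metadata

oral <- taxon_table(unclass(rt)[md$sample_id[md$habitat == "oral-like" &
                                             md$visit == 1], ])
vag  <- taxon_table(unclass(rt)[md$sample_id[md$habitat == "vaginal-like" &
                                             md$visit == 1], ])
fit_mle(oral, n_boot = 200, seed = 2)
#> DM fit (mle): K = 60 taxa, n = 100 subjects
#>   theta = 0.0489 (SE 0.0011)   logLik = -14981.79
fit_mle(vag, n_boot = 200, seed = 2)
#> DM fit (mle): K = 60 taxa, n = 100 subjects
#>   theta = 0.3955 (SE 0.0373)   logLik = -716.96
```

The oral-like habitat is 8× less overdispersed than the vaginal-like one:
oral communities are nearly interchangeable between subjects, while the
vaginal-like habitat's hyper-dominant genus collapses in a subset of
subjects. Alpha diversity tells the complementary story (the vaginal-like
habitat is the *least* diverse yet the *most* variable):

```r
ds <- diversity_summary(rt, md)
aggregate(cbind(richness, shannon) ~ habitat, ds, mean)
#>        habitat richness   shannon
#> 1    oral-like   32.915 2.8412970
#> 2    skin-like    5.630 1.1165565
#> 3   stool-like   12.830 1.6788972
#> 4 vaginal-like    2.120 0.2361714

stab <- temporal_stability(tab, md, "oral-like", depth = 1000, seed = 3)
mean(stab$spearman)
#> [1] 0.910
```

A between-visit Spearman of 0.91 marks the oral-like habitat as temporally
stable; the skin-like habitat's value is far lower. `run_pipeline()` (YAML
config in, TSV artifacts + manifest out) chains all stages with
per-stage derived seeds so reruns are byte-identical.

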