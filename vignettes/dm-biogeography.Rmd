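---
title: "Modelling between-subject variation of microbial communities with the Dirichlet-multinomial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling between-subject variation of microbial communities with the Dirichlet-multinomial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmbiogeo)
```

## The problem

Genus-level 16S rRNA surveys of human body habitats show two layers of
randomness. Within a sample, read counts are a multinomial draw from the
subject's underlying community. Between subjects of the same habitat, the
underlying communities themselves differ — mildly in some habitats (most
oral sites, stool), drastically in others (vaginal sites, where a single
genus usually dominates but collapses in a subset of women; skin, which is
environmentally exposed). Summaries that ignore the second layer conflate
sequencing noise with real biogeography.

`dmbiogeo` models both layers with the Dirichlet-multinomial (DM)
distribution and builds the surrounding habitat-characterisation pipeline:
depth standardisation, alpha/beta diversity, cross-habitat association,
prevalence–abundance structure, temporal stability across two visits, and
cross-cohort comparison.

## The model

For subject $i$ with counts $x_i = (x_{i1},\dots,x_{iK})$ and depth
$N_i = \sum_j x_{ij}$,

$$P(X_i = x_i) = \frac{N_i!}{x_{i1}!\cdots x_{iK}!}
  \frac{\prod_{j=1}^{K}\prod_{r=1}^{x_{ij}}
        \left[\pi_j(1-\theta) + (r-1)\theta\right]}
       {\prod_{r=1}^{N_i}\left[(1-\theta) + (r-1)\theta\right]},$$

where $\pi$ is the habitat-mean taxon-frequency vector and
$\theta \in [0,1)$ the overdispersion. $\theta = 0$ collapses to the
multinomial: every subject shares the composition $\pi$. Larger $\theta$
inflates the between-subject variance of each taxon's frequency,

$$\mathrm{Var}\!\left(\frac{x_{ij}}{N_i}\right)
  = \pi_j(1-\pi_j)\,\frac{1 + (N_i-1)\theta}{N_i},$$

so $\theta$ is a depth-free, community-wide measure of how much subjects
differ — the quantity this package exists to estimate. Equivalently the
model is a Dirichlet compound multinomial with concentrations
$a_j = \pi_j(1-\theta)/\theta$, $A = \sum_j a_j = (1-\theta)/\theta$; the
implementation works in this parameterisation throughout.

## Estimation

Two estimators are provided.

* `fit_moments()` estimates $\pi$ by read-pooled proportions (weighting
  subjects by depth, which has lower variance than the unweighted mean when
  depths vary) and solves the variance identity above for $\theta$, pooling
  across taxa by summing numerators and denominators. Pooling, rather than
  averaging per-taxon solutions, keeps the estimator stable when most taxa
  are rare. Negative raw estimates (underdispersed data) are clamped to 0
  with a warning.
* `fit_mle()` maximises the exact log-likelihood over the unconstrained
  log-concentration vector $\log a$ with its analytic gradient
  (L-BFGS-B), initialised from the moments fit. The coordinates are boxed
  to $[-25, 16]$: beyond $e^{16}$ the paired `lgamma` differences lose all
  significant digits to cancellation (the fit is then multinomial,
  $\theta < 10^{-7}$, to working precision), and below $e^{-25}$ a taxon is
  numerically absent. When the optimum sits on the $\theta = 0$ boundary
  the boxed interior iterate can be marginally dominated by the
  moments/multinomial fit; the better of the two is returned, so the MLE
  log-likelihood never falls below the moments fit. Taxa observed in no
  sample are excluded from the simplex before fitting and reported with
  $\pi_j = 0$.

Uncertainty for $\theta$ comes from a nonparametric bootstrap over subjects
(`theta_bootstrap()`, 200 replicates by default). A bootstrap was chosen
over an asymptotic (observed-information) standard error because the
estimate frequently sits near the $\theta$ boundary for stable habitats,
where the quadratic approximation is poor.

`theta_across_depths()` rarefies one table to several depths (1,000 /
3,000 / 6,000 / 9,000 reads by default), refits $\theta$ at each, and
declares the estimates consistent when every pair of per-depth 95%
bootstrap percentile intervals overlaps. Since $\theta$ is a population
parameter and rarefaction is a fair thinning of each sample, per-depth
estimates should agree on DM-distributed data; interval overlap was chosen
as the assessment because it needs no distributional assumption beyond the
bootstrap already in hand.

## Rarefaction and its contract

`rarefy_sample()` subsamples reads without replacement, so each taxon's
subsampled count is multivariate-hypergeometric — the contract, regardless
of mechanism. One draw per sample is the default (repeated-draw averaging
changes the variance structure silently). Every sample's draw is seeded
from the master seed and the *sample id*, with two consequences: draws are
reproducible independently of which other samples share the table, and two
identical tables rarefy identically — which makes self-comparison
identities (`habitat_association(A, A)` returning $\rho = 1$) exact rather
than approximate.

When two habitats are compared (`habitat_association()`), both are
subsampled to the minimum read count across the paired samples, so alpha
and beta comparisons are never confounded by depth.

## The synthetic generator

No public per-sample archive is bundled; instead `synthetic` scenarios
generate habitat-structured data from the same DM model the estimators
assume, which is what makes parameter-recovery and calibration testing
possible. A `habitat_scenario()` fixes $\pi$, $\theta$, the cohort size,
a depth distribution, and a `stability` weight; `make_scenario_suite()`
emits a two-visit study in which each subject's visit-2 latent composition
is `stability` parts the visit-1 latent draw and `1 - stability` parts a
fresh Dirichlet draw. Observed two-visit data constrain only the realised
between-visit correlation, not a dynamical model, so this mixture is the
simplest latent construction with a single interpretable knob. Each
subject's draws come from an RNG stream derived from (seed, habitat,
subject index), so enlarging a cohort never perturbs existing subjects.
Inter-visit intervals are drawn uniformly from 30–359 days, the observed
range of such two-visit designs.

`default_habitat_suite()` encodes four archetypes on a shared pool of
60 genera (each habitat's geometric abundance ranking rotated to a
different part of the pool, so the same genera recur everywhere with
different dominance orders, as in real habitats):

| habitat | $\pi$ shape | $\theta$ | stability |
|---|---|---|---|
| oral-like | geometric, ratio 0.93 (even) | 0.05 | 0.9 |
| stool-like | 0.45-dominant + geometric 0.80 tail | 0.08 | 0.9 |
| skin-like | geometric, ratio 0.60 (long tail) | 0.30 | 0.3 |
| vaginal-like | 0.90-hyper-dominant + geometric 0.50 tail | 0.40 | 0.4 |

with 100 subjects per habitat, two visits, and lognormal depths (median
3,000 reads, truncated at 1,200). The $\theta$ values place the stable
habitats below 0.1 and the variable ones at 0.3–0.4; evenness decreases as
overdispersion increases, the configuration observed in human habitats
(the most variable habitats are the dominated ones). These sizes keep a
full analysis under a minute while leaving estimator noise well below the
between-habitat contrasts of interest.

What the generator does *not* emulate: sequencing error, chimeras and
classifier mistakes (counts are taken as truth); seasonal or other
structured temporal effects; within-subject coupling between habitats
(habitats are generated independently, consistent with the near-zero
cross-habitat diversity correlations seen in real data, but an assumption
nonetheless). Tests passing on these data therefore validate the
statistical machinery, not robustness to upstream artefacts.

## Diversity, association, biogeography

* Shannon diversity uses the natural log (the convention of the ecology
  toolchain this package leans on). The unclassified bins are excluded from
  richness and Shannon by default — they are classifier artefacts, not
  taxa — with `include_unclassified = TRUE` available since the opposite
  convention is defensible.
* Habitat comparisons use Welch's t-test rather than the pooled-variance
  form: between-subject variances differ by an order of magnitude across
  habitats, exactly what $\theta$ measures. P-values are
  Bonferroni-multiplied by the number of pairs and capped at 1.
* Accumulation curves (`vegan::specaccum`, 500 random orderings) and
  rank-abundance curves break ties lexicographically for determinism.
* The Mantel test correlates upper triangles and computes
  $p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$ with 999
  permutations by default, the small-sample-safe convention.
* Spearman correlations use mid-ranks everywhere. Temporal stability is
  computed on relative abundances over the union of taxa observed in either
  visit, zeros kept; when that union is a single taxon, both visits are
  100% the same genus and the correlation is reported as 1 (the rank
  statistic is undefined on one point, but the community is maximally
  stable — leaving it `NA` would systematically drop the most dominated,
  most stable subjects).
* Prevalence means "at least one read" with no abundance floor: rare-taxon
  detection as a function of depth is one of the things being studied, and
  a floor would bake the answer in. Carrier-only means/SEs describe
  abundance *given presence*, which is what separates endemic
  (high-abundance, low-prevalence) from cosmopolitan taxa.
* Abundance quantiles use the median-unbiased order-statistic convention
  (`type = 8`), fixed and documented for reproducibility.
* Cohort overlap of prevalent genera (present in ≥ 50% of samples) is
  reported both as Jaccard and relative to the first cohort, because either
  denominator is defensible and they differ when cohorts differ in
  richness.
* Hierarchical clustering is complete linkage on Bray-Curtis; purity cuts
  the tree at $k = 2$ (configurable), matching two-project comparisons.
  Merge-height ties are broken by smallest index, `hclust`'s documented
  rule.

## Degenerate inputs and numerical edges

* `dm_log_pmf` returns $-\infty$ (not an error) when a taxon with
  $\pi_j = 0$ has reads, and reduces exactly to the multinomial at
  $\theta = 0$ via the empty-product convention.
* Tables with zero rows (all samples filtered) are legal and round-trip;
  all-zero taxon columns survive both I/O dialects.
* Fewer than 3 shared subjects makes cross-habitat correlations undefined
  and flagged, never silently `NA`-propagated; a constant interval vector
  flags `interval_vs_stability` undefined (no rank variance).
* Single-sample tables cannot be fit (between-subject variance is the
  estimand); the error says so.

## Limitations

The estimators assume exchangeable subjects within a habitat; structured
covariates (age, sex, geography) are not modelled — a DM regression is out
of scope. $\theta$ summarises community-wide variation in one number and
will under-describe habitats where a few taxa are hypervariable against a
stable background. The temporal model is a one-knob mixture, adequate for
ordering habitats by stability but not for forecasting. Cross-cohort
comparison quantifies, but does not correct, batch effects.
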