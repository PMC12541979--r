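# coresat

Core/satellite partitioning and community analysis for microbiota count data.

Cross-sectional amplicon studies of the gut microbiome routinely ask two
questions: which taxa form the *common core* of a cohort and which are rarer
*satellites*, and how do community structure and predicted function differ
between study groups (for example, a healthy control group and two disease
subtypes)? `coresat` implements that full analysis as a tested, reproducible R
pipeline operating on ordinary taxon-by-sample count tables, for microbial
ecologists and clinical microbiome researchers who would otherwise stitch the
steps together across several GUI tools.

## The analysis

**Partitioning.** For every taxon in a group, compute its distribution
*d* (percent of the group's samples in which it occurs) and its mean percent
relative abundance *ā* over those positive samples. The distribution–abundance
relationship is the OLS regression of log₁₀ *ā* on *d*, reported with R²,
*F*(1, n−2) and *P*. Taxa with *d* ≥ 75 % are labelled **core**, the rest
**satellite**; the fit of core abundances to the log-normal distribution is
checked by a χ² test on equal-probability bins (df = bins − 3).

**Diversity.** Fisher's log-series α — the root of *S* = α ln(1 + *N*/α) —
per sample on the whole, core and satellite submatrices (raw counts), plus
Shannon *H′* on reads rarefied to even depth; groups compared by
Kruskal–Wallis with pairwise Mann–Whitney U under Bonferroni correction.

**Community structure.** Bray–Curtis dissimilarity
*d(j,k)* = Σᵢ|xᵢⱼ−xᵢₖ| / Σᵢ(xᵢⱼ+xᵢₖ); within/between-group similarity
summaries; ANOSIM (rank-based *R* with permutation *P*, exact enumeration
available for small designs, Bonferroni-adjusted pairwise runs); SIMPER
decomposition of between-group dissimilarity into per-taxon contributions
(which sum exactly to the mean between-group dissimilarity); PCoA with 95 %
normal-theory ellipses.

**Predicted function.** KO contribution tables (as produced by
metagenome-prediction tools) aggregated to KEGG level-3 pathways, stratified
by the core/satellite partition, filtered to pathways holding > 1 % of total
predicted functionality, CLR-transformed (multiplicative half-minimum
pseudocount) and compared across groups by ANOVA or Kruskal–Wallis with
Benjamini–Hochberg adjustment; satellite-exclusive pathways identified by
construction.

**Constrained ordination.** RDA (on Hellinger-transformed abundances) and CCA
(on relative abundances) with forward selection of clinical covariates: each
candidate's added inertia is tested by a Monte-Carlo pseudo-F with
reduced-model residual permutation.

A synthetic-cohort generator (`sim_config()` / `simulate_counts()`) plants all
of this structure — log-normal core abundances, occupancy–abundance coupling,
group-specific satellite expansion, satellite-exclusive pathways — so every
stage can be validated against ground truth.

## Worked example

```r
library(coresat)
library(dplyr)

sim      <- simulate_counts(sim_config(seed = 42))   # 3 groups x 12 samples
counts   <- remove_singleton_taxa(sim$counts)
metadata <- sim$metadata

summary_tbl <- summarize_taxa(counts, metadata)
fit <- fit_distribution_abundance(filter(summary_tbl, group == "HC"))
fit
#> Distribution-abundance regression (group HC)
#>   slope = 0.01578, intercept = -1.393 (log10 abundance)
#>   R^2 = 0.552, F(1,189) = 232.73, P = 8.92e-35, n = 191
```

A strongly positive occupancy–abundance relationship justifies the split:
widely distributed taxa are also the locally abundant ones.

```r
partition <- partition_taxa(summary_tbl, threshold = 75)
partition_abundance_share(counts, partition, metadata) |>
  group_by(group) |> summarise(core_pct = mean(core_pct))
#> # A tibble: 3 × 2
#>   group core_pct
#> 1 D1        77.7
#> 2 D2        75.9
#> 3 HC        83.0
```

The core taxa hold most of the reads in the control group (HC); in both
disease groups (D1, D2) the satellite fraction has expanded — the planted
disease signature.

```r
d <- bray_curtis(to_relative_abundance(counts))
anosim(d, metadata, n_perm = 999, seed = 1)
#> ANOSIM: R = 0.1524, P = 0.003 (999 permutations, n = 36, groups: D1, D2, HC)
pairwise_anosim(d, metadata, n_perm = 999, seed = 1)
#> # A tibble: 3 × 5
#>   comparison statistic p_value n_perm p_adjusted
#> 1 HC vs D1      0.252    0.002    999      0.006
#> 2 HC vs D2      0.0901   0.075    999      0.225
#> 3 D1 vs D2      0.138    0.018    999      0.054
```

Composition differs across the three groups overall (R = 0.15, P = 0.003),
driven mainly by the control-vs-D1 contrast — the pattern the pipeline is
designed to detect and decompose (follow with `simper()`, `pcoa()` +
`autoplot()`, and `forward_select()` for the covariate analysis).

`run_pipeline(config, out_dir)` chains every stage from a single
configuration (a list or YAML file, naming either input paths or a simulation
config) and writes all artefacts plus a manifest of file hashes; a rerun with
the same configuration and seed is bit-identical.

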