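---
title: "Methods: core/satellite partitioning and downstream community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core/satellite partitioning and downstream community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresat)
```

This vignette documents the statistical model behind each stage of the
pipeline, the parameters a user can turn, the numerical conventions adopted
where the field's practice is not unique, and what the synthetic-cohort tests
do and do not establish about real data.

## The core/satellite model

The pipeline's organising idea is the occupancy–abundance relationship of
community ecology: in most communities, taxa found in many samples also tend
to be locally abundant. Plotting each taxon's distribution $d$ (the percentage
of a group's samples in which it occurs) against the log of its mean percent
relative abundance $\bar a$ over those positive samples typically shows a
significant positive regression, which licenses splitting the community at a
prevalence threshold into a *common core* ($d \ge$ threshold) and rarer
*satellite* taxa. Core taxa are interpreted as the community's principal
functional contributors; satellites as a more opportunistic subcommunity that
expands under perturbation.

Conventions adopted, and why:

* **Abundance axis.** $\bar a$ is log10-transformed before the regression
  (`fit_distribution_abundance(log_abundance = TRUE)`); taxon mean abundances
  span orders of magnitude and the log-normal is the community-ecology default
  for abundance distributions. The choice is recorded in the fit object and
  can be turned off.
* **$\bar a$ averages over positive samples only.** Occupancy information
  lives entirely in $d$; mixing zeros into $\bar a$ would double-count it.
* **Distribution is in percent** (0–100). This affects the slope's scale
  only, not R², F or P.
* **Threshold.** Default 75 % (inclusive: $d \ge 75$ is core), the convention
  for small cohort studies; `partition_taxa(threshold=)` exposes it.
  Core sets are monotone in the threshold (tested property).
* **Log-normal goodness of fit.** Core-set $\log_{10}\bar a$ values are fit by
  sample mean and SD, binned into $k = \max(4, \lceil\sqrt n\rceil)$
  equal-probability bins under the fitted normal (adjacent bins merged until
  every expected count is at least 1), and the Pearson $\chi^2$ is referred to
  $k_{\text{final}} - 3$ degrees of freedom (two estimated parameters; floor
  of 1). Fewer than 8 core taxa gives a result flagged `reliable = FALSE`
  rather than an error, since a tiny core set cannot support the test.

## Preprocessing

Counts enter as taxon-by-sample integer tables (an orientation flag transposes
sample-major files; the amplicon-standard taxon-major layout is the default,
since the layout of third-party exports varies). Two rules run before any
analysis:

* **Singleton removal**: taxa whose total count across the whole dataset is
  exactly 1 are dropped (the usual post-denoising artefact filter). A taxon
  seen once in each of two samples is kept.
* **Species-level collapsing**: rows whose full seven-rank lineage is
  identical down to species are summed into one OTU. Equality is
  case-sensitive on the whole lineage so homonymous species in different
  genera never merge; rows without a species assignment pass through
  untouched. Per-sample totals are conserved exactly.

Relative abundances (percent) are computed after both steps; the alternative
order (normalise, then collapse) changes nothing for the collapse itself but
would make the singleton rule depth-dependent, so normalisation comes last.

## Diversity

Fisher's $\alpha$ solves $S = \alpha\,\ln(1 + N/\alpha)$ by bracketed root
search on $(10^{-10}, 10^{10})$ with one Newton polish; every returned value
satisfies the defining equation to better than $10^{-8}$. It is computed on
**unrarefied** counts: $\alpha$ is designed to be insensitive to $N$, and
subsampling first would only discard information. Shannon $H'$ (natural-log
units) is computed on counts rarefied without replacement to a common depth —
evenness measures do respond to depth — with the depth defaulting to the
minimum sample total. Group differences use Kruskal–Wallis plus pairwise
Mann–Whitney U with Bonferroni correction; the Mann–Whitney P value is exact
(enumeration) when $n_1 n_2 \le 400$ with no ties, and a tie-corrected normal
approximation with continuity correction otherwise.

## Community structure

Bray–Curtis dissimilarities are computed on percent relative abundances.
ANOSIM ranks all off-diagonal dissimilarities (mid-ranks for ties) and
contrasts between- versus within-group mean ranks, scaled by $n(n-1)/4$; the
P value is the permutation estimator $(1 + \#\{R^\ast \ge R\})/(1 + B)$ with
$B = 9999$ by default, counting the observed labelling among the extremes so
P can never be 0. For small designs `exact = TRUE` enumerates every distinct
label assignment instead. Pairwise ANOSIMs are Bonferroni-multiplied by the
number of pairs.

SIMPER splits each between-group pair's Bray–Curtis dissimilarity into
per-taxon terms and averages over pairs; the per-taxon averages sum *exactly*
to the mean between-group dissimilarity (a conservation identity the tests
assert to $10^{-10}$). SIMPER runs on the same percent-abundance scale as the
distance matrix, so its decomposition is of the matrix actually tested.

PCoA double-centers $-\tfrac12 D^2$ and keeps the axes with positive
eigenvalues; negative eigenvalues (Bray–Curtis matrices are generally not
Euclidean-realisable) are dropped and reported — count and total magnitude —
rather than corrected, the common practice for visualisation-grade
ordination. Percent variance is quoted relative to the positive part. Group
ellipses are normal-theory: centre at the group mean, axes from the
eigendecomposition of the group covariance scaled by
$\sqrt{\chi^2_{2,0.95}}$; a rank-deficient covariance flags a degenerate
ellipse instead of erroring.

## Predicted function

KO contribution tables are aggregated to level-3 pathways with the standard
hierarchy convention: a KO mapped to $k$ pathways contributes its full
abundance to each (no splitting). Unmapped KOs are excluded and counted.
Stratification keeps only contributions from taxa labelled core (or
satellite) in the contributing sample's own group, then renormalises within
the stratum; a sample with nothing left in a stratum is dropped from that
stratum's tests with a warning. The "> 1 % of total predicted functionality"
filter is strict and applied to the pooled table (not per group), so the same
pathway set is tested in every group.

The CLR transform replaces zeros by a multiplicative pseudocount of half the
smallest positive value in the table — zero cells get the pseudocount, the
positive cells of the same sample shrink proportionally so the sample total
is preserved — and then centres each sample's logs. Per-sample CLR values sum
to zero by construction (asserted to $10^{-9}$). Group comparisons on CLR
values default to classical ANOVA (the heatmap-comparison route), with
Kruskal–Wallis on the untransformed shares exposed through the same function;
both are reported by the pipeline since rank- and mean-based routes answer
slightly different questions and the field uses both. Benjamini–Hochberg
controls the FDR across pathways; pairwise Mann–Whitney tests use Bonferroni.

Satellite-exclusive pathways are those with positive abundance somewhere in
the satellite stratum and zero everywhere in the core stratum — a set
comparison, not a test.

## Constrained ordination

RDA regresses the column-centered response matrix on the covariates and takes
the variance of the fitted values as constrained inertia; the explained
fraction equals $1 - RSS/TSS$ of the multivariate least-squares fit (asserted
to $10^{-8}$ against an independent `lm.fit`). Species abundances are
Hellinger-transformed for RDA, the standard linearising transform; CCA runs
on relative abundances in the chi-square metric with row weights. Categorical
covariates are dummy-coded against a first-level reference and tested as a
block (df = levels − 1); collinear columns are dropped and reported.

The pseudo-F for a candidate conditions on the already-selected covariates:
$(Δ\text{inertia}/df_Δ)\,/\,(\text{residual inertia}/df_{res})$, with the
null distribution from permuting the rows of the reduced-model residuals
(999 permutations by default) and the same $+1$ P-value estimator as ANOSIM.
Forward selection ranks the remaining candidates by added inertia, tests them
in that order, adds the first one at or below `alpha` (default 0.05), and
stops when none qualifies; every tested candidate is kept in an audit trail.
An empty selection is a valid outcome.

## The synthetic cohort generator

`simulate_counts()` emulates a three-group faecal 16S cohort: per-taxon mean
percent abundances are log-normal (log10 mean −0.5, SD 0.5); satellites are
shrunk by `satellite_abundance_scale` (default 0.15, chosen so the control
group's core taxa hold roughly three quarters of the reads, as reported for
healthy-control faecal cohorts in this literature); presence is Bernoulli
around class baselines (core 0.95, satellite 0.30) with a logistic coupling
of slope `da_slope = 1.5` to the taxon's centred log abundance, which is what
produces the significant positive distribution–abundance regressions
downstream; disease groups multiply satellite abundances by
`disease_satellite_expansion` (default 2.0) before renormalisation; reads are
multinomial at `depth = 50000` per sample (12 samples per group, 40 core +
160 satellite taxa), with optional Dirichlet overdispersion for robustness
experiments. Column sums equal the depth exactly and everything is
deterministic per seed. The pathway generator plants a taxon-by-pathway
Bernoulli incidence with a reserved satellite-only block; its ground truth
lists *every* pathway without a core carrier, including pathways that end up
core-free by chance of the incidence draw, so exclusivity recovery can be
checked as an exact set identity.

**Recovering the planted expansion.** Because each sample is renormalised,
the naive disease/control ratio of mean satellite share has expectation
$2(C+S)/(C+2S) < 2$ under a planted factor of 2 — at realistic satellite
shares it sits near 1.6. `estimate_satellite_expansion()` therefore uses the
satellite *odds* $s/(100-s)$, whose group geometric-mean ratio responds
multiplicatively to the planted factor and recovers it without that bias; the
tests assert the naive direction (disease share above control) separately.

**What the generator does not emulate:** taxonomic assignment error and its
ASV-level fragmentation, sequencing error and chimeras, compositional
interactions between taxa (abundances are independent given the draw),
longitudinal repeat sampling, covariate–community confounding (the clinical
covariates it emits are independent noise), and realistic pathway genomics
(incidence is Bernoulli, not phylogenetically structured). Passing the
recovery tests therefore shows the estimators are correct under the stated
model, not that the model captures every feature of real cohorts.

**Effect sizes.** At the default conditions the group effect on community
structure is deliberately moderate — permutation pseudo-F near 1.3–1.6 — so
that the pipeline is exercised in the regime such pilot studies actually
occupy. Forward selection consequently ranks the group factor first by added
inertia essentially always, while its permutation P crosses 0.05 in only
about two thirds to three quarters of cohorts; the suite's guarantee that a
*strong* covariate is selected first is demonstrated on a planted
strong-covariate design where power is not the limiting factor.

## Numerical conventions and problem sizes

* Root-finding tolerance for Fisher's $\alpha$: machine-level (`uniroot` at
  $\varepsilon^{0.75}$ plus one Newton step); acceptance bound $10^{-8}$ on
  the residual.
* Permutation counts: 9999 (ANOSIM) and 999 (pseudo-F) by default; the test
  suite uses 99–199 and the calibration checks use 199 with 500–1000 null
  replicates, sizes chosen to keep the full suite under a couple of minutes
  while leaving the binomial error on a 5 % rejection rate well inside the
  ±2-percentage-point assertion band.
* Ties: mid-ranks everywhere a rank test is involved.
* The pipeline driver expands one global seed into per-stage seeds by fixed
  offsets, so stages can be rerun independently yet reproducibly, and hashes
  every output file into a manifest that also records each defaulted
  parameter (threshold, transform, pseudocount policy, permutation counts).

## Known limitations

* ANOSIM is sensitive to within-group dispersion differences; a significant R
  can reflect dispersion rather than location. The analysis tradition this
  package implements uses ANOSIM, so no PERMANOVA/PERMDISP alternative is
  provided.
* The log-normal GOF test at small core sizes (n < ~20) has limited power;
  its role is descriptive support for the threshold, not model selection.
* CLR results depend on the zero-replacement policy at very sparse tables;
  the half-minimum multiplicative rule is simple and scale-preserving but not
  the only defensible choice.
* CCA's permutation test permutes residuals in the chi-square metric with
  fixed row weights; with wildly uneven sample totals a weighted permutation
  scheme could be preferable.
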