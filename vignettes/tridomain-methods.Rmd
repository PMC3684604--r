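---
title: "Cross-domain gut microbiome and diet associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-domain gut microbiome and diet associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tridomain)
```

## The scientific problem

Marker-gene surveys of human stool census three Domains of life at once:
bacteria (16S rRNA), archaea (archaeal 16S) and fungi (ITS1). The archaeal
community is typically dominated by one of two lineages — the methanogen
*Methanobrevibacter* or the ammonia-oxidizing *Nitrososphaera* — which
rarely co-occur; the bacterial community is organized along a reciprocal
*Prevotella*/*Bacteroides* abundance axis; and the fungal community splits
between the phyla Ascomycota and Basidiomycota. The analytical question is
how these communities relate to each other and to diet, measured by two
nutrient inventories: a food-frequency questionnaire capturing *usual*
(long-term) diet and a multi-day recall capturing *recent* diet.

`tridomain` implements this analysis graph end to end: strict table IO,
inclusion filters, within-amplicon proportions, taxonomy-derived UniFrac
distances, distance-based permutation tests, pairwise association
statistics with FDR tiers, nutrient dimension reduction, and a seeded
synthetic cohort generator that makes every stage testable without any
sequence data.

## Data model and inclusion filters

Counts are genus × sample integer matrices, one per Domain
(`count_table`). Taxonomy is a ranked lineage of length L = 5 (Phylum,
Class, Order, Family, Genus) per genus, with the sentinel `"unclassified"`
for missing ranks. When OTU-level tables are supplied,
`aggregate_otus_to_genus()` first drops OTUs with fewer than 5 total reads,
then sums surviving OTUs into genera; lineages unclassified at genus rank
are pooled into `Other_<lowest classified rank>` buckets rather than being
discarded.

The inclusion rules are applied in a fixed order:

1. **sample depth** — a sample is retained if it yielded at least 200
   sequences; this rule is specific to the fungal ITS libraries (the
   bacterial and archaeal tables default to no depth rule);
2. **proportions** — each retained sample column is divided by its own
   sum, i.e. proportions are computed *within each amplicon* on the full
   genus table, before rare genera are removed;
3. **genus inclusion** — a genus enters the testing set if it is present
   in at least 9 samples *and* has at least 10 reads in total.

All three thresholds are inclusive boundaries. Computing proportions
before the genus filter means a sample's proportions always refer to its
complete amplicon, not to the filtered subset; the `FilterReport` records
the order and every dropped item with the single rule that triggered it.

## Taxonomic distance and taxonomy-derived UniFrac

With no phylogeny available across three Domains, between-genus distance is
taken from the rank hierarchy:

$$d(i,j) = 1 - k/L,$$

where $k$ counts consecutive ranks, from the Phylum down, at which the two
lineages agree. The `"unclassified"` sentinel never matches anything —
including another `"unclassified"` — so comparison stops at the first
unknown rank of either lineage. This is deliberately conservative: shared
ancestry is never invented for incompletely classified genera.

This distance is an ultrametric, and its tree *is* the rank hierarchy:
`taxonomy_to_tree()` materializes one internal node per distinct nested
rank label with unit branch lengths, rather than re-clustering the distance
matrix (which would introduce a dependence on linkage arbitration). Leaves
sit at depth L, and the leaf-to-leaf path length divided by $2L$ reproduces
the formula exactly — a property the test suite checks against independent
cophenetic computation. Unclassified ranks open a private path for their
genus. The tree can be exported as Newick via `ape`.

On this tree, for samples A and B with branch descendant-proportion totals
$p_{Ai}, p_{Bi}$ and branch lengths $b_i$:

$$d^{(\alpha)}(A,B) \;=\; \frac{\sum_i b_i\,(p_{Ai}+p_{Bi})^\alpha
\dfrac{|p_{Ai}-p_{Bi}|}{p_{Ai}+p_{Bi}}}{\sum_i b_i\,(p_{Ai}+p_{Bi})^\alpha},$$

skipping branches with $p_{Ai}+p_{Bi}=0$. $\alpha = 1$ is the
weighted-normalized form (`weighted_unifrac()`), small $\alpha$
de-emphasizes abundant lineages, and the presence/absence form
`unweighted_unifrac()` uses branch occupancy indicators. The default
$\alpha$ grid for omnibus testing is $\{0, 0.5, 1\}$. Samples whose
amplicon yielded no reads get `NA` distances and are excluded pairwise,
never imputed.

## PERMANOVA and the multi-distance omnibus

`permanova()` uses the Gower-centred inner-product matrix
$G = -\tfrac12 J D^{2} J$ and the hat matrix $H$ of the design (intercept
plus covariate; regression form for continuous covariates such as the
*Prevotella*/*Bacteroides* ratio or a nutrient-cluster score, one-hot form
for group labels):

$$F \;=\; \frac{\mathrm{tr}(HGH)/q}{\mathrm{tr}\big((I-H)G(I-H)\big)/(n-q-1)}.$$

Significance comes from permuting sample labels with the add-one counting
rule $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$, so $p$ is never
0 and the attainable floor is $1/(n_{perm}+1)$. The default permutation
count is 9,999; every API takes an explicit seed, and identical seeds give
identical p-values.

`permanova_g()` combines several distance matrices (e.g. the generalized
UniFrac family) into one omnibus test: the observed statistic is the
minimum over matrices of the per-matrix permutation p-value, and its null
distribution is built from the *same* permutations applied jointly to all
matrices, respecting their dependence. With one matrix (or the same matrix
twice) the omnibus p equals the single-matrix p.

Unequal within-group dispersion is a known confounder candidate for
distance-based tests. `unequal_variance_simulation()` generates two groups
with equal centroids and dispersion ratios 1, 2 and 4 and reports the
empirical rejection rate at $\alpha = 0.05$; ratio 1 doubles as the type-I
calibration.

## Association statistics

- **Co-occurrence** (`dice_matrix()`): genera are "present" at a
  within-amplicon proportion of at least 0.01 (inclusive); the Dice index
  $S = 2|A\cap B|/(|A|+|B|)$ is computed over sample-presence sets pooled
  across all three Domains. Heatmap ordering (`dice_cluster_order()`) uses
  Ward clustering on Euclidean distances between Dice profiles (each
  genus's row of S). A pair of never-present genera is assigned 0 (not
  `NaN`) so the matrix stays complete for clustering.
- **Archaeal status** (`classify_archaeal_status()`): each sample is
  labelled *Methanobrevibacter*, *Nitrososphaera* or `none` by the
  predominant focal lineage; an exact abundance tie is unresolvable and
  falls back to `none` with a warning (ties do not occur in practice —
  co-occurring lineages differ substantially in abundance).
- **Kruskal–Wallis / Dunn**: `kruskal_wallis()` wraps the standard
  tie-corrected chi-square test; the fully degenerate case (all values
  equal) is defined as $H = 0$, $p = 1$. `dunn_posthoc()` computes pairwise
  $z = \Delta \bar R / SE$ with the tie-corrected
  $SE = \sqrt{(N(N+1)/12 - \sum(t^3-t)/(12(N-1))) (1/n_i + 1/n_j)}$ and BH
  adjustment across pairs.
- **Spearman** (`spearman_matrix()`): average-rank (tie-handled) rho per
  feature pair with two-sided p from the t approximation; constant
  features yield flagged `NA` results excluded from the FDR family.
- **Fisher's exact** (`fisher_exact_2x2()`): two-sided by the
  minimum-likelihood convention (sum of tables no more likely than
  observed), stated explicitly because "two-sided Fisher" has competing
  conventions.
- **BH-FDR tiers** (`bh_fdr()`): step-up q-values with the heatmap tier
  convention — FDR 25/20/15/10% earn 1–4 asterisks. Each heatmap panel is
  its own FDR family (fungi × bacteria; genera × archaeal status; nutrient
  clusters × status; clusters × genera), matching per-analysis adjustment;
  q-values are never shared across panels.
- **P/B ratio** (`pb_ratio()`):
  $\log_{10}((p_{Prev}+10^{-6})/(p_{Bact}+10^{-6}))$; the pseudocount keeps
  absent genera finite while preserving monotonicity.
- **z-score summaries** (`group_zscore_summary()`): per-feature z-scores
  across all samples, then group means — the normalized heatmap statistic;
  size-weighted group means sum to zero by construction.

## Dietary dimension reduction

`nutrient_cluster_measurements()` reduces ~200 nutrients to 20 surrogate
covariates (about 10% of the panel): pairwise Spearman correlation,
dissimilarity $\sqrt{1-\rho}$ (the square root makes the Ward embedding
well behaved), Ward agglomeration cut at `n_clusters`, then per cluster a
correlation PCA (members z-standardized first — nutrients have
incommensurate units) whose PC1 score per sample is the *nutrient cluster
measurement*. Two conventions make scores reproducible: PC1 is oriented so
its correlation with the mean of member z-scores is non-negative (PCA signs
are otherwise arbitrary), and a singleton cluster's score is the z-scored
nutrient itself. Scores are invariant to affine rescaling of raw nutrients.
The usual and recent inventories are clustered separately.

`screen_and_posthoc()` implements the two-stage workflow: stage 1 screens
every cluster score against each community distance matrix by PERMANOVA
(raw $p < 0.05$ per pair by default — the screen is a gate, not an
inference, so no multiplicity correction is applied at this stage); stage 2
computes, for screened-in clusters only, Spearman correlations with every
genus proportion and Kruskal–Wallis tests across archaeal status, each
family BH-adjusted at FDR 25%.

## The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analysis assumes, under one seed. Its defaults are the study conditions of
a 96-sample three-domain survey:

- archaeal occupancy states with probabilities 24/96
  (*Methanobrevibacter* only), 10/96 (*Nitrososphaera* only), 6/96 (both,
  with fixed 80/20 shares so the predominance rule is always decidable),
  the remainder archaea-free; three minor archaeal genera at 2% occupancy;
- fungal occupancy 0.89/0.57/0.42 for *Saccharomyces*, *Candida*,
  *Cladosporium*, nine mid-prevalence and twelve rare genera, so that
  about 12 fungal genera are expected in ≥ 9 samples; fungal (and
  bacterial) sequences are guaranteed in every sample, as observed in real
  surveys;
- a latent reciprocal *Prevotella*/*Bacteroides* axis and a latent
  reciprocal Ascomycota/Basidiomycota axis on the log scale;
- counts drawn as multinomial reads at log-normal depth (~1,000
  reads/sample) from Dirichlet proportions (concentration 200), so columns
  carry realistic overdispersion;
- two nutrient inventories with 20 exchangeable correlation blocks of 10
  nutrients (within-block rho 0.7), plus a planted upward shift of the
  "carbohydrate" block factor in methanogen-positive samples;
- planted taxon–diet effects as Gaussian copulas: a tilt
  $t = \rho f + \sqrt{1-\rho^2}\,\varepsilon$ couples a genus to a
  nutrient-block factor $f$ at rank correlation $\rho$ (default effects:
  *Candida* and *Prevotella* with block 1 at $\rho = 0.5$, *Bacteroides*
  with block 2), and planted taxon–status log-shifts (*Candida*,
  *Saccharomyces*, *Ruminococcus* up and *Bacteroides* down in
  methanogen-positive samples).

Effect injection acts on the latent scale end to end: the tilt shifts both
the genus's Dirichlet mean (abundance) and its occupancy logit
(detection). The injection gain defaults to the saturation regime in which
the observable association is governed by the planted copula correlation
$\rho$ alone rather than by the gain — this is what makes $\rho$ the
meaningful planted parameter recorded in the ground truth. Without the
occupancy coupling, random presence/absence would dilute a planted
$\rho = 0.5$ to an observable rank correlation near 0.1, contradicting the
generator's own contract.

What the generator does *not* emulate: read-level errors, chimeras and
contamination; taxonomic misassignment; compositional coupling between
Domains beyond the planted axes; seasonal or repeated-measures structure;
and realistic nutrient marginals (blocks are Gaussian). Passing tests
therefore demonstrate correctness and calibration of the statistical
machinery under the assumed data model, not robustness to the full
messiness of real amplicon data.

## Numerical choices and degenerate inputs

- Proportion columns must sum to 1 within 1e-9; distance symmetry within
  1e-12; permutation tie comparisons use a 1e-12 slack so exact ties count
  as exceedances (conservative).
- All-zero samples: proportions stay zero and the sample is flagged;
  UniFrac emits `NA` with a warning; the pipeline drops such samples from
  distance-based stages.
- Constant covariates are an error in PERMANOVA ("zero-variance
  covariate"); constant nutrients are excluded with a warning before
  clustering; constant taxa yield flagged `NA` correlations outside the
  FDR family.
- Presence threshold 0 marks everything present (0 ≥ 0); use a positive
  threshold for nonzero detection.
- Dice of two never-present genera is 0; the diagonal is always 1.

## Problem sizes used by the test and acceptance suites

The suites run entirely on generated data: oracle-equivalence checks use
toy trees and 20 × 30 fixtures with exhaustive enumeration at $n = 4$ for
the permutation test; calibration uses 1,000 null replicates at $n = 30$
samples and 199 permutations (the add-one rule is exact at level 0.05 on
that permutation grid); recovery uses 20 cohorts for block-membership ARI,
100 cohorts at $n = 96$ for planted-effect power through the two-stage
workflow, and 200 reduced null cohorts ($n = 48$, 60 nutrients) for the
stage-2 false-selection rate. These sizes were chosen to make Monte-Carlo
error small relative to the property bounds being checked.

## Known limitations

- Taxonomy-derived UniFrac treats all rank steps as equally long; it is a
  coarse stand-in for a true phylogeny, and distances between genera in
  different phyla saturate at 1.
- PERMANOVA is implemented for a single covariate (regression or one-hot
  groups); multi-factor designs with interactions and dispersion tests
  (PERMDISP) are out of scope.
- The min-p omnibus for several distance matrices is one reasonable
  combination rule; others (e.g. Fisher combination) would weight the
  family differently.
- The stage-1 diet screen at raw p < 0.05 trades false negatives for
  family-size reduction in stage 2; the threshold is configurable and its
  choice materially affects downstream power.
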