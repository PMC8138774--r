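---
title: "Consensome meta-analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensome meta-analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(consensomeR)
```

## The analytic problem

Individual case-control transcriptomic studies of a disease such as
non-alcoholic fatty liver disease (NAFLD) disagree on which genes are
differentially expressed: cohorts differ in platform, severity mix, and
power. The consensome approach sidesteps single-study noise by asking a
frequency question instead: *across many independent case-control
datasets, how often is each gene discovered?* Genes discovered far more
often than chance are "confidence transcripts" (CTs) — a reduced-bias
disease signature that can then be interrogated with gene-set and
transcriptional-regulator enrichment, or compared against a model system
such as a chimeric human/mouse liver.

This package implements that stack end to end: per-dataset two-group
differential statistics, the discovery-rate meta-analysis with an exact
significance model, orthology-mapped cross-species comparison (including
the H:M relative-expression gene set), hypergeometric over-representation
with odds ratios, and a synthetic-data generator that emulates the
statistical structure of the whole design so every stage can be validated
against planted ground truth.

## Per-dataset differential statistics

Each dataset is reduced to a table of per-gene statistics by `de_table()`:

* **Normalization.** Counts-per-million (`1e6 * count / column sum`), the
  simplest library-size correction; `normalize = "none"` is available for
  already-normalized input.
* **Test.** Student's or Welch's two-sided t-test on
  `log2(normalized value + pseudocount)`. The log transform stabilizes the
  variance of count-like data enough for the t family; the default
  pseudocount of 0.5 keeps zeros finite while being negligible against
  typical CPM values (hundreds).
* **Fold change.** `(mean_case + pc) / (mean_control + pc)` on the linear
  normalized scale, with `log2fc = log2(fold_change)` by construction.
* **Degenerate rows.** All-zero genes are retained with `p = 1` and flag
  `"allzero"`; rows with zero variance in both groups but separated means
  get `p = 0` and flag `"degenerate"` rather than `NaN`. Tables are sorted
  by p with ties broken by identifier so output is deterministic.

On null negative-binomial simulations the pooled type-I error of this
pipeline is close to nominal (≈0.048 at α = 0.05 across 20 datasets of
2,000 genes in the test suite), which is what the meta-analysis layer
assumes — approximately, and it does not need more, because the null
rates it uses are empirical (below).

## The consensome model

Let gene *g* be measured in *D* datasets and discovered (two-sided
p < α, default α = 0.05, strict) in *d* of them. Under the null that
discoveries are independent Bernoulli events with per-dataset
probabilities α⁽ʲ⁾, the discovery count is Poisson-binomial, and the
consensome p-value is the exact upper tail

> p = P(X ≥ d), X = Σⱼ Bernoulli(α⁽ʲ⁾),

computed by dynamic programming over the full distribution
(`poisson_binomial_tail()`; exact, numerically stable for the ≤ 100
datasets this design contemplates — each convolution step is a convex
combination of probabilities, so no cancellation occurs). Two choices
matter:

* **Empirical null rates** (default): α⁽ʲ⁾ is the *observed* fraction of
  measured genes with p < α in dataset *j*, not the nominal α. A
  miscalibrated or batch-affected dataset then inflates its own null
  rather than every gene's significance. `null_mode = "nominal"` is kept
  for calibrated inputs and for closed-form verification.
* **Direction-agnostic discovery**: a gene counted as discovered may go up
  in one cohort and down in another; direction enters through the
  fold-change summary instead. This matches ranking genes "by the
  frequency with which they are upregulated or downregulated".

Across the universe (genes measured in ≥ `min_datasets` datasets, default
3 — discovery rates over one or two datasets are too unstable to rank),
p-values get Benjamini-Hochberg correction, and genes are ranked by
(q ascending, discovery rate descending, |log2 geometric-mean fold change|
descending, identifier). The tie-break chain makes the ranking a total
order, so statements like "23rd of 18,162" are reproducible. The reported
`percentile` is `100 * rank / |universe|` (small = strong). The
geometric mean is the right average for ratios: fold changes of 2.0 and
0.5 cancel to 1.0.

`confidence_transcripts()` applies the CT rule: q < `q_max` (default
0.05) with an optional fold-change filter (`mean_fc > fc_min` for `up`,
`< 1/fc_min` for `down`; default `fc_min = 1.25`).

```{r consensome-demo}
cfg <- simulation_config(n_genes = 500, n_datasets = 6, seed = 1)
sim <- simulate_consensome_studies(cfg)
cons <- build_consensome(sim$collection)
head(cons, 3)
ranking_auc(-cons$rank, cons$id %in% sim$truth$true_genes)
```

## Cross-species chimeric comparison and the H:M set

In a chimeric liver, human and mouse hepatocytes experience the same diet
in the same organ, so their differential responses can be compared
directly — after mapping genes through a strict 1:1 orthology map
(ambiguous pairs are dropped and counted; the human:mouse statistic is
undefined for many-to-many mappings).

`map_orthologues()` joins the two species' differential tables and
computes the **H:M ratio**: the ratio of human to mouse case-condition
(Western-diet) group means after *within-species* CPM normalization with
a pseudocount. Normalizing within species first is deliberate: the two
compartments differ in size (chimerism percentage), so only relative
expression is comparable. The ratio uses case-state means because the
scientific question is relative expression in the steatotic state.

`overlap_counts()` partitions pairs significant in at least one species
into six disjoint cells (shared up/down, human-only up/down, mouse-only
up/down). One convention was genuinely open: a pair significant in *both*
species with *opposite* directions. We assign it to the human-only cell
of its human direction — the human compartment is the reference in this
design — which keeps the six cells disjoint and summing to the number of
pairs significant in ≥ 1 species. `hm_filter()` implements the H:M rule:
significant in both species and `hm_ratio > ratio_min` (default 1.2,
strict). Direction concordance is *not* required by default, since the
ratio rule is about relative expression level rather than response sign;
`require_concordant = TRUE` switches the stricter reading on.

## Enrichment and node-HCT intersections

`hypergeom_overlap()` is the classical over-representation test: for a
query of size *n* and reference set of size *K* in a universe of size
*N*, with overlap *k*, it reports the exact upper tail P(X ≥ k) (the
standard convention, equal to one-sided Fisher on the 2×2 table) and the
plain cross-product odds ratio, with explicit 0 (k = 0) and infinity
(empty off-diagonal) handling; a Haldane-Anscombe 0.5 correction is
available but off by default because uncorrected ratios are what this
analysis style reports. The universe should be the set of genes the query
could have come from — for CT enrichment, the consensome universe.

`hct_intersection()` runs the same test for every node of a library of
high-confidence transcriptional target (HCT) sets, corrects across nodes
with Benjamini-Hochberg, and sorts by (q, p, node id); nodes with
q < 0.05 are the conventional significant intersections. The HCT library
itself is treated as given input (GMT format): deriving HCTs from
ChIP-seq evidence is upstream of this package.

A note on testing calibration: the hypergeometric tail is discrete, so a
Kolmogorov-Smirnov test against the uniform applied to raw p-values of
exchangeable random nodes is biased by construction (the empirical CDF
plateaus below each support point). The suite therefore checks
calibration through the randomized probability integral transform
`u = p − U·pmf(k)`, which is exactly Uniform(0, 1) if and only if the
reported tails are correct.

## The synthetic-data generator

`simulate_consensome_studies()`, `simulate_chimeric_experiment()` and
`simulate_hct_library()` generate inputs with the statistical structure
the downstream stages assume, plus ground-truth labels, so recovery is
measurable. The count model is negative binomial with gene-level
log-normal means (`meanlog = 4`, `sdlog = 1` by default, i.e. typical
means of roughly 7–400 counts) — the standard overdispersed RNA-seq-like
model, and approximately what the t-test-on-log stage assumes.

Two dispersion regimes are used, following the usual biological
coefficient of variation (BCV) conventions:

* **Clinical cohorts** (consensome simulation): dispersion 0.16
  (BCV 0.4, typical for human data), 10 cases vs 10 controls per dataset,
  10 datasets, 5% true genes, per-dataset replication probability 0.7,
  planted |log2FC| = 1. Each true gene's direction is drawn once and held
  fixed across datasets (discovery is direction-agnostic, but the mean
  fold change needs a coherent direction to be meaningful).
* **Chimeric liver** (genetically identical mice, one donor): dispersion
  0.01 (BCV 0.1), `meanlog = 5`, 8 vs 8 — matching the group sizes of
  such designs.

The chimeric simulator plants five labelled sets over identity-paired
orthologues (`HG…`/`MG…`): shared up, shared down, human-only,
mouse-only, and the `hm_high` set. The `hm_high` genes are repressed in
*both* species, but more strongly in mouse
(human effect −e, mouse effect −e − log2(hm_ratio)), so the case-state
H:M ratio equals `hm_ratio` (default 2.4) while both species remain
significantly differential — the structure of cholesterol-biosynthesis
enzyme genes whose diet repression is weaker in human hepatocytes. The
naive alternative of scaling the human mean *up* would have destroyed the
human significance that the H:M rule requires.

Determinism: one global seed drives every draw, with per-dataset seeds
derived as `seed + dataset index`, so datasets are independent but the
whole collection is byte-reproducible.

What the generator deliberately does **not** emulate: platform and
probe-mapping heterogeneity across cohorts, correlated gene modules,
batch effects, the heavy low-expression tail of real libraries,
compositional distortion from a few dominant transcripts, and
cross-dataset differences in sample size or severity. Passing recovery
tests therefore demonstrates that the pipeline's statistics are correct
and well calibrated under its stated model — not that any particular
clinical consensome is reproduced. The published clinical statistics
(e.g. a 25-gene severity signature at OR = 12.3 in an 18,162-gene
consensome over 20+ cohorts) require retrieving and reprocessing the
original public datasets and HCT libraries, which is outside this
package's scope.

## Numerical choices and degenerate inputs

* All thresholds are strict (`p < alpha`, `q < q_max`,
  `hm_ratio > ratio_min`): boundary values are excluded, everywhere.
* `share_percent()` rounds half-up to one decimal, the convention used in
  reported percentages (so 6.25% prints as 6.3).
* Ties: differential tables sort by (p, id); the consensome by
  (q, rate, |log2 mean FC|, id); HCT results by (q, p, node id).
* Zero-variance and all-zero rows produce flagged finite output, never
  `NaN` (see above).
* The Poisson-binomial DP carries the full mass function; it sums to 1
  within 1e-12 and reduces exactly to the binomial when rates are equal.
* Pipeline manifests hash every artifact with MD5 (`tools::md5sum`) —
  the purpose is re-run comparison, not cryptography.

## Problem sizes in the test suite

The validation suite simulates 2,000 genes × 10 datasets (20 samples
each) for consensome recovery, 2,000 orthologue pairs at 8 vs 8 for the
chimeric comparison, and a 50-node × 200-gene HCT library over an
18,000-gene universe — large enough for stable recovery statistics (the
planted-label AUROC, exact H:M set recovery, rank-1 planted node) while
keeping a full run in tens of seconds. Exhaustive-enumeration oracles
(all 2^D Poisson-binomial outcomes for D ≤ 12; all C(N, n) hypergeometric
draws for N ≤ 12) pin the exact statistics to ≤ 1e-12.

## Known limitations

* The consensome null treats datasets as independent and genes as
  exchangeable within a dataset; correlated cohorts (shared controls,
  re-analysed series) would make the Poisson-binomial tail anti-
  conservative.
* The t-on-log approach is a pragmatic approximation for counts; at very
  low expression its calibration degrades, which is why the empirical
  null mode is the default upstream of the meta-analysis.
* The H:M ratio assumes within-species CPM makes compartments comparable;
  strong compositional shifts between species would bias it.
* Orthology is restricted to 1:1 pairs; genes with paralogous expansions
  are excluded from cross-species statements.
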