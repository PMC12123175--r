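---
title: "Subphenotype-to-genotype discovery for autism with disproportionate megalencephaly"
author: "asdmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subphenotype-to-genotype discovery for autism with disproportionate megalencephaly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asdmtools)
```

## The analysis this package implements

Roughly 15% of autistic boys show disproportionate megalencephaly (ASD-DM):
a brain large relative to height. The subphenotype carries poorer cognitive
prognoses and is thought to share genetic etiology with autism itself, which
makes it a lever for gene discovery: restricting a de novo variant scan to
probands with the subphenotype concentrates signal that is diluted in
unselected autism cohorts. `asdmtools` implements that strategy end to end
as reusable, tested components:

1. **Growth phenotyping** — convert head circumference, height and cerebral
   volume to age- and sex-referenced z-scores and percentiles, call
   macrocephaly and megalencephaly, and partition macrocephalic probands
   into three subtypes.
2. **Trio variant filtering** — identify de novo, rare, likely
   gene-disruptive variants from family genotypes, include qualifying
   copy-number calls, aggregate to candidate genes with recurrence and
   constraint flags, and compute burden statistics.
3. **Network expansion and ontology enrichment** — expand candidate gene
   sets over a scored interaction edge table and test ontology-term
   enrichment against a background universe.
4. **Zebrafish validation statistics** — rank-sum comparisons of larval
   morphometric features with Bonferroni stars, delta-delta-Ct qPCR
   quantification, and a single-cell expression stage that tests whether a
   designated gene set (FMRP targets) shifts down when the candidate gene
   is overexpressed.
5. **Synthetic data** — generators for every input with machine-readable
   ground truth, so the full pipeline runs and is tested with no external
   data access.

## Growth phenotyping

Reference standards are sex- and age-indexed mean/SD tables
(`growth_reference()`); z-scores interpolate mean and SD linearly in age
within sex, and percentiles are `100 * pnorm(z)` under a normal assumption.
If a reference file carries empirical percentile columns they can be used
directly, but the default normal conversion is what all rules below assume.

Macrocephaly uses a permissive cutoff: head-circumference z strictly above
1.5 SD. The 1.5 SD cutoff is often glossed as "the 90th percentile"; under
normality it is in fact the 93.3rd. We treat the SD rule as primary and
report the exact percentile alongside, since the two cannot both be the
operative rule. Macrocephalic probands are then assigned exactly one
subtype:

* **SO** (somatic overgrowth): head circumference *and* height percentiles
  both strictly above 90 — checked first, so the three classes partition;
* **DMac** (disproportionate): height percentile over head-circumference
  percentile strictly below 0.7;
* **RM** (relative): the remainder (ratio at or above 0.7; the boundary is
  assigned to RM as the complement class, recorded in the output metadata).

All inequalities are strict, exactly as written; `call_head_size()` stamps
the resolved rule constants into its output so downstream consumers can see
which convention produced the calls. Megalencephaly is the analogous strict
1.5 SD exceedance of the cerebral-volume/height ratio against age-matched
references. Ages up to 3 months outside the reference range are clamped to
the nearest tabulated age; beyond that is an error rather than an
extrapolation.

```{r growth-demo}
ref <- gen_growth_reference()
hc <- growth_reference("head_circumference_cm",
                       ref[ref$measure == "head_circumference_cm", ])
ht <- growth_reference("height_cm", ref[ref$measure == "height_cm", ])
cohort <- gen_growth_cohort(sim_config(seed = 1, cohort = list(
  n_probands = 500, macro_fraction = 0.4)))
calls <- call_head_size(cohort$cohort, hc, ht)
table(calls$subtype)
```

## Trio variant filtering

De novo detection compares the proband's alternate alleles with both
parents at the same variant key. Raw string comparison of VCF records
misses representation differences (multiallelic rows, unnormalized indels),
so variants are first split per alternate allele and reduced to a minimal
left-aligned representation (`normalize_variant()`, the classic
trim-and-shift algorithm) before keys are compared. Sites where a parent
genotype is missing are excluded from de novo calls — the conservative
choice, mirroring the separate treatment of probands without parental data,
for whom rarity is defined as absence from dbSNP instead of the population
frequency rule.

Qualifying variants are **likely gene-disruptive** (frameshift, stop-gain
or splice-site, taken from the supplied annotation; no re-annotation is
attempted) and **rare** (frequency strictly below 0.2% in all five
continental reference populations, with a missing population treated as
zero). Copy-number calls enter when precise, exonic and impacting at most
two genes. Candidate genes count distinct probands (recurrence), credit
every gene a CNV impacts, and flag constraint at pLI > 0.9. Multi-gene
variant annotations are counted for all listed genes and flagged rather
than resolved arbitrarily.

Burden comparisons use a 1-df chi-squared test on carrier-rate 2x2 tables
(no continuity correction by default, with a toggle, since either
convention is defensible) and a two-sided Fisher's exact test for gene-set
by group tables; degenerate zero-margin tables return p = 1 with a warning
rather than an error.

## Network expansion and enrichment

The interaction network is a plain scored edge table (the STRING
`protein.links` dialect is accepted), thresholded at a combined score of
400 — the conventional medium-confidence cutoff, configurable since the
operative threshold is rarely printed. Each seed contributes its top 10
interactors by descending score with lexicographic tie-breaking (a
documented deterministic rule; ties at the k-th position would otherwise
make results depend on row order). The expanded node set is the union of
seeds and interactors, with induced edges retained and node origin
recorded; the result is independent of seed iteration order.

Term enrichment is the hypergeometric upper tail of the query/term overlap
within a user-supplied background, Benjamini-Hochberg adjusted across
terms. The EASE variant (overlap reduced by one, as popularized by DAVID)
is available by flag; the standard hypergeometric is the default. Term
pooling — merging similar terms into one gene set — is driven by an
explicit user-supplied grouping table; no automatic semantic pooling is
attempted. `ontology_coverage()` reports the fraction of a gene set
annotated to at least one pooled term.

## Morphometrics and qPCR

Larval features (total area, body length, eye distance, telencephalon
width, head-trunk angle, brain areas; FishInspector export column names are
accepted as aliases) are compared with a two-sided Wilcoxon rank-sum test.
The implementation enumerates the exact permutation distribution of the
rank sum whenever the combined sample is small (at most 12, valid with
ties), uses the classical exact U distribution for larger tie-free samples
up to 25 per group, and otherwise a tie-corrected normal approximation with
continuity correction. Fold change is the median ratio — robust and
consistent with a rank test; a mean ratio is available by flag since
"fold change" is rarely defined precisely in figure legends.

Bonferroni adjustment multiplies by the family size — by convention the
features tested in one experiment (four gross morphometric features, or two
brain areas), configurable because family membership is a design choice.
Stars use inclusive thresholds on the adjusted p (0.05 / 0.01 / 0.001).
Knockdown efficiency is quantified by delta-delta-Ct with group-mean Ct
values and fold change `2^(-ddCt)`; replicate-level fold changes are
returned for dispersion checks, but no error model is imposed.

## Single-cell expression stage

Cells with mitochondrial or ribosomal percentage above 5, fewer than 200
detected features (strictly below; 200 exactly is retained), more features
than the sample mean plus 2 SD, or a doublet flag are removed, with a
per-rule report. Normalization is per-cell depth scaling to the median
library size with a natural-log `log1p` transform. This deliberately
replaces a regularized variance-stabilizing transform: the downstream
result surface (rank-sum differential expression, enrichment, shift tests)
depends only weakly on the variance-stabilization flavor, and the simpler
transform is exactly reproducible and dependency-free. Optional per-gene
residualization on mitochondrial/ribosomal percentages is provided.
Variable genes are ranked by the variance of standardized counts (expected
SD from a loess mean-variance trend, clipped; a Poisson expectation is used
below 50 genes where a trend fit is meaningless).

Clustering is PCA (30 components by default; component signs fixed by
forcing the largest-magnitude loading positive, removing the usual SVD sign
indeterminacy) followed by Euclidean-distance agglomerative clustering with
Ward linkage — the unstated-linkage default here, with complete and average
available — and a dendrogram cut at k (10 broad; 18 within brain cells).

Before differential expression, the perturbed condition is downsampled
without replacement to the control total while preserving its own cluster
proportions (largest-remainder allocation, `min(available, target)` per
cluster, deterministic under seed). That is one reading of "sampled with
respect to the original cluster distribution to match control cell counts";
the alternative reading — match the control's per-cluster counts — is
provided as `mode = "per_cluster"`.

DE tests genes detected in at least 1% of either group with an absolute
log2 fold change of at least 0.1, where the fold change is
`log2((mean(expm1(test)) + 1e-9) / (mean(expm1(control)) + 1e-9))` on the
log layer — the conventional definition those thresholds imply. Two
detection floors appear in published descriptions of this analysis ("1% of
cells" for DE, "0.01% of cells" for the gene-set shift analysis); both are
kept, as separate configurable parameters (`min_pct = 0.01` and
`expression_floor = 1e-4`). Target-set enrichment is a two-sided Fisher
test of DEG-by-target status over the expressed background, BH-adjusted
across a configurable family of sibling tests (the adjustment family is a
config list because it is rarely stated). The shift analysis computes the
per-gene average log2 fold change per model with the DE-style group-mean
definition (the within-cell averaging alternative is noted but not used),
then runs a paired t-test between models over shared target genes and
unpaired t-tests of target versus non-target genes within each model.

## What the generators emulate — and what they do not

The synthetic module exists so every stage is exercisable offline with
known truth. Defaults are the study conditions at desk scale: a cohort of
2,000 probands with a 40% planted macrocephalic fraction (drawn from the
truncated tail above 1.5 SD) and head-height z-correlation 0.5; 3 trio
families with 5,000 Mendelian inherited variants and 50 planted de novos
each, a 30% likely-gene-disruptive fraction and Beta(0.2, 50) population
frequencies with a point mass at zero (so both branches of the rarity
filter are exercised); an Erdos-Renyi interaction graph (300 genes, mean
degree 8, scores uniform on 150-999) with one planted enriched term; 35
larvae per group with a 0.96x body-length effect and 5% coefficient of
variation; and 500 cells per condition over 2,000 genes in 5 clusters with
negative-binomial dispersion 0.5 (typical droplet-scale overdispersion)
and a 0.8x downshift on a 50-gene target set in the overexpression analog.

Real data differ in ways the generators do not model: growth references
are LMS-smoothed rather than normal; genotypes carry errors and mosaicism;
interaction networks are scale-free with hub structure; single-cell data
have ambient RNA, batch effects and far more cells and genes. Passing
tests therefore demonstrate correctness of the statistical machinery and
the filtering logic under clean, known-truth conditions — not robustness
to every artifact of real cohorts.

One honest limitation of "exact planted-truth recovery" deserves note: the
upper feature-count QC rule is *sample-relative* (mean + 2 SD), so any
stochastic generator produces natural violators of it at a ~2% rate. The
generator therefore records planted violators of the three absolute rules
only, and the exact-recovery test disables the relative rule; the relative
rule is verified separately on constructed data.

## Numerical choices and scales

Tolerances against enumeration oracles are 1e-10 or tighter. Exact-test
checks enumerate all 2x2 tables with grand total up to 30 and
hypergeometric configurations exhaustively to background 60 plus a
deterministic grid to 200; rank-sum enumeration covers all group-size
pairs with combined n up to 12, with and without ties. Calibration and
recovery simulations use 20 replicates at 500 cells per condition and
2,000 genes, and the reproducibility check runs the full pipeline twice at
a reduced demo scale (300 probands, 2 families, 150 cells per condition
over 400 genes, with the feature-count floor scaled to that gene universe).
These sizes were chosen so the whole suite runs in minutes on a laptop
while keeping every estimate's Monte Carlo error well inside the asserted
margins.

## Known limitations

* Percentiles assume normal references; skewed anthropometric measures
  would need LMS-style references, which are out of scope.
* No genotype-error or parental-mosaicism model: de novo precision/recall
  of 1.0 holds for error-free genotypes by design.
* The normalization is not a variance-stabilizing transform; variable-gene
  rankings can differ from regularized methods on real data.
* Hierarchical clustering with Ward linkage is O(n^2) in cells; the stage
  is sized for the tens of thousands of cells typical of targeted
  experiments, not atlas-scale data.
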