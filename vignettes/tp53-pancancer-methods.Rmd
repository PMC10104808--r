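---
title: "Methods: pan-cancer TP53 mutation classes, consensus expression and the immune microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer TP53 mutation classes, consensus expression and the immune microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tp53pancan)
```

`tp53pancan` implements a complete pan-cancer analysis of *TP53* mutations
on tabular inputs: somatic mutation calls (MAF dialect), a normalized
gene-by-sample expression matrix, sample annotations with subtype
stratifiers, a variant functional-annotation table, and optional immune
cell-abundance scores. This vignette is the package's account of the
statistical procedures, the tunable parameters, the synthetic-data
generator used for validation, and the design decisions taken where the
design was genuinely open.

## The two-step mutation classification

Tumor status is a deterministic rule over MAF variant-classification terms:
a tumor is TP53mut iff it carries at least one missense, nonsense, splice
site, translation-start-site, non-stop, frameshift or in-frame indel in
*TP53*; silent, UTR, intron, flank, splice-region and intergenic records —
and the absence of any record — leave a tumor TP53wt. Silent records are
therefore deliberately retained at parse time.

Qualifying variants are then assigned functional classes against an
annotation table keyed by the exact protein-change string (no fuzzy
codon-level matching — reproducible and dialect-stable):

* in the table: **GOF** when GOF-annotated, even if LOF is co-annotated
  (GOF takes precedence); **LOF** when LOF-annotated and not GOF; **DN**
  when DN-annotated, otherwise **non-DN**;
* absent from the table: **LOF** (and non-DN) when the MAF term is evidence
  of truncation (nonsense, frameshift, splice site, translation start site,
  non-stop); otherwise **VUS**.

Tumor-level flags are the union over the tumor's qualifying variants, so a
tumor can be simultaneously GOF and DN — necessarily so, since the observed
class overlaps (e.g. 90% of GOF tumors also DN) are only possible with
non-exclusive flags. A tumor carrying both a DN and a non-DN variant is a
member of both groups; contrasts that compare DN against non-DN exclude such
tumors from both sides to keep the groups disjoint (logged). VUS variants
make a tumor TP53mut but put it in no analysis class.

## Hotspot recurrence and homogeneity

A variant is recurrent iff some cancer type has at least
`hotspot_min_count = 2` carrier tumors **and** prevalence at least
`hotspot_min_prev = 1%`. The prevalence denominator is the number of
TP53-mutant tumors of the type by default; whether the screen should instead
use all tumors of the type is genuinely ambiguous, so both denominators are
computed and `tp53_config(hotspot_denominator=)` selects which drives the
screen. Variants without a protein-change key cannot be tallied and are
excluded (logged).

Prevalence intervals are exact Clopper–Pearson bounds from Beta quantiles,
implemented directly from the definition (`lower = 0` at `x = 0`,
`upper = 1` at `x = m`) and cross-checked in the test suite against
`binom.test` and the closed forms `1 − (α/2)^{1/m}` at the boundaries.
Cross-type homogeneity is the multi-group chi-square test of equal
proportions (`prop.test` with the continuity correction disabled uniformly,
so the statistic is the plain Pearson X² for any number of groups);
degenerate tables (all zero or all full) return p = 1. BH correction at
`fdr_q = 0.10` is applied across all recurrent variants.

## Fixed-sample-size differential expression

Expression values are consumed as upper-quartile-normalized linear values
and transformed once to `log2(x + 1)`; the offset handles zeros and is
configurable. Duplicate gene rows collapse to the row with the largest
total signal — deterministic and conventional for collapsed identifiers.

Each contrast compares exactly `n_sub` tumors per group (10, 15 or 20;
default 15) drawn uniformly without replacement. Fixing n makes the
significant-gene counts comparable across cancer types and contrast types —
the point of the design — at the cost of discarding information in large
groups. The subsample seed is `seed XOR hash(cancer type, group names)`, so
adding contrasts never perturbs existing ones, and a cell whose groups
cannot fill `n_sub` returns an explicit N.A. marker rather than an error or
a smaller-n analysis. One draw per contrast is the default (mirroring the
single random selection of the reference design); repeated draws with a
median-count summary are available through the caller by varying the seed.

Per gene, the two-sided Wilcoxon rank-sum test is used: the exact null
distribution when the combined group size is ≤ 25 and the gene is tie-free,
otherwise the normal approximation with mid-ranks, tie-corrected variance
and continuity correction. Zero-variance genes get p = 1. The fold change is
the difference of group means on the log2 scale (the mean is continuous with
the Gaussian generator below; a median-based FC would also be defensible).
BH flags use FDR 10% throughout.

## Pan-cancer consensus

Per-type p-values are combined with Fisher's method,
`X² = −2 Σ ln pᵢ ~ χ²(2k)` over the k available types; zero p-values are
clamped to the smallest positive double with a warning. Consensus membership
counts the cancer types with raw (unadjusted) p < `alpha_raw = 0.05`,
irrespective of direction, and requires at least `consensus_threshold = 16`
of the 24 types. The threshold is fixed: types where a gene was unmeasured
reduce the numerator but not the threshold. Direction is a strict majority
of the per-type log2-FC signs; ties resolve by the sign of the summed FC and
are logged. Direction-agnostic counting was chosen because membership is
defined by differential expression alone, with direction assigned afterwards
by vote; mixed-direction genes are therefore possible and visible in the
output.

The member FC matrix is bi-clustered with Manhattan (L1) distance and
average linkage (UPGMA), rows and columns independently; `NA` entries are
imputed as 0 (no evidence of change) before clustering. Default cuts are 6
gene clusters and 3 type clusters, matching the granularity at which strong/
moderate/weak over- and underexpression patterns separate; both are
configurable, and the dendrograms export as Newick. Type clusters are tested
against per-type TP53mut prevalence with the Kruskal–Wallis rank-sum test
(the chi-square approximation; with one observation per cluster the result
is flagged small-sample).

## Over-representation and the enrichment fold change

Enrichment of a query list against a catalog uses the two-sided Fisher exact
test on `[[k, K−k], [n−k, N−n−K+k]]`, with the standard minimum-likelihood
tail-summation rule for two-sidedness; direction is carried by the
enrichment fold change `FC = (k/K)/(n/N)`. The universe N is always the
union of the catalog's member genes — each catalog reproduces its own FCs
transparently, since published universes are rarely printed — and query
genes outside the universe are dropped rather than added to N. Single-list
analyses correct across the catalog's categories; per-cancer-type grids
(types × categories, separately for over- and underexpressed lists) are
corrected jointly across the whole grid, the conservative reading of a
grid-wide FDR.

## TMB and the immune microenvironment

TMB is the per-sample count of missense mutations in the genome-wide MAF
after removing duplicate identical records; samples absent from the MAF
count 0. Subtype labels stratify HNSC/CESC by HPV status, STAD/UCEC/COAD/
READ by MSI-H vs MSI-L/MSS, and BRCA by receptor subtype (up to 32 subtypes
from 24 types); samples with an unknown stratifier are excluded from that
type's subtype analyses. Each (subtype, population) pair and (subtype, TMB)
is a two-sided Wilcoxon test of TP53mut vs TP53wt with at least two profiled
tumors per group; BH is joint across all tested pairs (per-subtype scope is
available), and the direction of a significant pair is the sign of the
median difference, consistent with the rank test. The deconvolution that
produces the abundance scores is out of scope: abundances are an input with
a documented schema.

## The synthetic cohort generator

The generator emits the full input bundle with known truth, and its defaults
are the validation study design used by the test suite and the acceptance
script:

* **Cohort**: the 24 cancer-type codes of the reference cohort, 30 samples
  each, mutation fraction 0.5 (15 mutant + 15 wildtype per type; counts are
  round-half-up of `n × fraction`, recorded in the manifest). Stratifier
  labels are drawn per type (HPV ~50/50, MSI-H ~35%, receptor subtypes
  ~45/30/25), giving the full 32-subtype grid.
* **Variants**: each mutant tumor draws one variant from a weighted catalog
  (optionally a second, to exercise multi-variant aggregation); 10% of
  wildtype tumors get a silent *TP53* record to exercise wildtype calling.
  The default catalog emulates the observed spectrum: ~65% missense / 26%
  truncating / 7% splice, an 89% share of p.R175H within codon 175, and
  database annotations giving roughly a third GOF and half DN tumors. Per
  cancer-type weight matrices allow planting type-specific hotspots.
* **Expression**: log2-scale Gaussian, `baseline(type, gene) +
  δ·1[mutant] + ε`, `ε ~ N(0, σ²)` with σ = 1 log2 unit. 100 planted
  overexpressed genes with δ = 2 active in a random 20 of the 24 types
  (per gene); underexpressed genes are available but default to 0 since the
  recovery benchmark is defined on the up-signature. Values are emitted on
  the linear scale as `2^x − 1`, so the reader's `log2(x + 1)` recovers the
  planted values exactly; log2 values are clamped at zero (linear values
  must be non-negative), a negligible-rate event under the default
  baselines. A Gaussian model at the normalized-expression level — not a
  count model — matches what the rank-based pipeline consumes and keeps
  oracle comparisons exact.
* **TMB**: per-sample missense counts are Poisson with mean 40, multiplied
  in mutant tumors by 2 in 15 subtypes and 0.5 in 5 (the planted TMB
  pattern), emitted as genome-wide background MAF records.
* **Immune**: 14 generic population scores, `base + shift·1[mutant] +
  N(0, 1)`, with planted shifts in 12 of 32 subtypes (6 exclusively down, 4
  mixed, 2 exclusively up). The shift magnitude of 3 noise SDs was chosen by
  a power calculation so that planted shifts are recoverable with high power
  even in the smallest stratified subtypes of the default design (~5 mutant
  vs ~9 wildtype tumors) under joint FDR control.

What the generator does **not** emulate: count-level sequencing noise,
normalization artifacts, gene–gene correlation (genes are independent given
status, so FDR behavior on real, correlated transcriptomes will be less
sharp than in these tests), copy number/LOH, tumor purity, and the
deconvolution step behind the immune scores. Passing tests demonstrate that
the statistical machinery recovers structure of the planted kind at the
planted scale; they do not certify performance on real cohorts.

## Numerical choices and degenerate inputs

* Exact Wilcoxon refuses ties and falls through to the corrected
  approximation; zero-variance genes return p = 1.
* Fisher's method returns NA on an empty p-vector, clamps p = 0 with a
  warning, and uses `df = 2k` over available values only.
* Clopper–Pearson raises on `m = 0`; the homogeneity test raises on a
  single group and returns 1 on degenerate tables.
* Cohort filtering (≥ 7 TP53-mutant tumors per type) raises when nothing
  survives; it is idempotent.
* Sample harmonization is exact string matching after whitespace trimming —
  no barcode-truncation heuristics, avoiding silent mis-joins; callers must
  pre-harmonize identifiers.
* Bi-clustering raises when the requested cluster count exceeds the items.

## Problem sizes used in validation

The test suite and acceptance script run three synthetic studies: the
default design above (720 samples × 500 genes) for consensus, immune and
classification recovery; the same design with no planted effects for null
calibration (the raw p < 0.05 rate across 24 × 500 gene tests, and the
immune false-positive count against its FDR budget); and a 120-samples-per-
type cohort so that the mutation classes reach the fixed n = 15, where the
class-vs-class contrasts (no class effects planted) stay empty — no
significant genes in the large majority of analyzable cells and almost never
more than one — while the mutant-vs-wildtype contrasts on the same cohort
detect dozens to hundreds of genes. These sizes were chosen as the smallest
at which every stage of the design is exercised with non-trivial power.

## Known limitations

* The consensus threshold (16 of 24) is calibrated to a 24-type cohort;
  other cohort sizes need a rescaled `consensus_threshold`.
* One subsample draw per contrast reproduces the reference design but
  inherits its sampling variance; the seed policy makes this variance
  reproducible, not smaller.
* Class contrasts exclude dual-membership tumors (DN and non-DN via
  different variants), slightly shrinking both groups.
* The enrichment universe is catalog-relative; fold changes are not
  comparable across catalogs with very different universes.
* Survival analysis and mutational-signature attribution are out of scope.
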