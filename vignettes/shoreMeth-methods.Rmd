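---
title: "shoreMeth: models, parameters and design choices"
author: "shoreMeth authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shoreMeth: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoreMeth)
```

shoreMeth analyses subtype-structured DNA methylation measured by
affinity capture (MBDCap-seq style) and summarised as relative
methylation scores (RMS, values in [0, 1]) over fixed 100-bp bins,
together with gene expression and per-CpG pileup counts, for a panel of
breast cancer cell lines labelled luminal, basal A or basal B. This
vignette explains the statistical procedures, the tunable parameters and
their defaults, the synthetic-data generator used to validate the
pipeline, and the design choices made where the methodology was
genuinely open.

## Data model

The central container is `BinnedMethylation`, a
`RangedSummarizedExperiment` whose rows are a non-overlapping 100-bp
tiling of the genome (`makeBinIndex()`), whose single assay `rms` holds
the per-bin per-sample methylation score, and whose `colData$subtype`
carries the subtype factor. Region annotation lives as a per-bin label
set (`rowData(x)$labels`, a `CharacterList`) drawn from the vocabulary
CpGI, shore, shelf, promoter, exon, intron, UTR5, UTR3, TFBS, gene,
intergenic, plus the derived intersections `promoter_CpGI` and
`promoter_shore`. Inside R all coordinates follow the `GRanges`
convention (1-based, closed); every BED or TSV interval file read or
written is 0-based half-open.

## Region derivation

CpG islands are inputs; shores are the 2,000-bp flanks on each side of
every island minus any island overlap, and shelves the next 2,000 bp
outward minus islands and shores, so the three classes are disjoint by
construction and per-class summaries are well defined. The 2-kb widths
are the common island-centric annotation convention; they are parameters
(`shoreWidth`, `shelfWidth`) because the convention is not universal.
Promoters are the 2,000 bp upstream of the TSS, strand-aware (the TSS of
a minus-strand gene is its interval end). A bin receives a region label
if it overlaps the region by at least 1 bp; this is the simplest rule
consistent with averaging "all bins overlapping" a feature, and it makes
multi-labelling (e.g. a bin that is both intron and shore) explicit
rather than hiding it behind a priority scheme.

## Differential methylation and DMRs

Each subtype pair (luminal/basal A, luminal/basal B, basal A/basal B) is
compared per bin with a Welch two-sample t-test; Welch rather than
pooled-variance because subtype groups routinely differ in variance and
the cost at equal variances is negligible. Multiplicity is controlled by
Bonferroni at adjusted p < 0.05, with the multiplier equal to the number
of bins actually tested in that pair: bins with an NA cell or zero
variance in both groups carry no hypothesis and are skipped (their
counts are reported). The hypomethylated pair member per significant bin
is the one with the lower group mean; exact ties are recorded as `tie`
and excluded from ratio numerators and denominators (a measure-zero
event under continuous noise). Significant bins merge into DMRs when
consecutive and direction-homogeneous; `maxGapBins` (default 0) permits
a run to bridge that many intervening non-significant bins. The
hypomethylation ratio of a region class is, among significant bins
carrying that class, the fraction whose hypomethylated member is a given
subtype; the two ratios of a pair sum to one whenever defined, and an
empty class yields NA rather than zero.

## Island-relative meta-profiles

The meta-profile axis has five 100-bp flank positions on each side of
the island (±500 bp) and 20 island-internal slices (5% steps; the
percent scale is what makes islands of different lengths comparable). A
position's value for one island and sample is the length-weighted mean
RMS of the bins overlapping that position's interval; islands then
contribute equally to the curve (an unweighted mean over islands), so a
handful of very long islands cannot dominate the profile. Flank
positions that fall off a chromosome are missing for that island and
excluded from the average. Islands shorter than the slice count are kept
with a warning (their slices share bins). The per-position subtype test
is a one-way ANOVA on the per-sample island-averaged values — one value
per sample, so the hundreds of islands are never treated as independent
replicates — with Bonferroni correction over axis positions. This is the
conservative choice; testing per island-position would inflate
significance through pseudo-replication.

## TFBS methylation and expression coupling

A TFBS's methylation in a sample is the unweighted mean RMS of all bins
overlapping it (TFBS are short, typically within one or two bins, and
the unweighted mean is the literal reading of averaging the overlapping
bins). The screen keeps TFBS that lie in a promoter/shore overlap, tests
subtype differences per TFBS by Kruskal–Wallis with Benjamini–Hochberg
FDR < 0.1 across TFBS, computes the Spearman correlation between TFBS
methylation and the downstream target gene's expression across all 30
samples (not within subtype: the hypothesis is that methylation
differences *between* subtypes drive expression differences), and
requires rho < −0.5. To separate methylation effects from TF-abundance
effects, a TF must itself have subtype-similar expression: we
operationalise "similar" as a Kruskal–Wallis p ≥ 0.05 on the TF's own
expression, symmetric with the differential test used elsewhere. ChIP
validation enters as a boolean input flag on each TFBS. Genes with at
least one TFBS passing all four screens are reported with their best
(most negative) rho, minimal FDR, and the subtype with the lowest mean
TFBS methylation; the fraction of reported genes hypomethylated in basal
B is attached to the table.

## Mutation calling and stratified rates

Mutation calls are made from per-site per-sample (coverage, mismatch)
counts with a one-sided binomial tail test against a sequencing-error
rate of 0.002 (roughly Q27): an observation is mutated when
P[X ≥ mismatches | coverage, error] < 1e-3 and coverage ≥ 10 reads.
Coverage above 250 reads is capped with proportional subsampling of
mismatches. This count-based caller deliberately replaces pileup
machinery (base alignment quality, anomalous-pair filtering): the
analysis only consumes binary calls, and users with real data can supply
calls from any caller through the same table schema. The minimum
coverage of 10 is our floor for a meaningful carrier-fraction estimate;
the error rate, call level and floor are all parameters.

Mutation rates are stratified by the methylation of the site's
containing bin into 0.05-wide RMS strata ([0.95, 1] closes the last
stratum). The rate is mutated site-sample observations over eligible
(covered) site-sample observations; an affinity-capture assay only
covers methylated regions, so uncovered sites are unobservable and are
excluded from denominators, and an empty stratum is NA rather than
zero. Subtype differences per stratum are tested by one-way ANOVA on
per-sample rates — per-sample because pooled subtype rates leave no
replication for ANOVA at all — with Bonferroni over the strata tested.

A site is subtype-specific when at least 30% of one subtype's samples
carry the call while each other subtype stays below 10%; with these
thresholds a site can match at most one subtype, and the implementation
refuses configurations with `minIn <= maxOut` where assignment could be
ambiguous. Regional counts of specific sites use the multi-label bin
annotation; the per-region subtype test is again a one-way ANOVA on
per-sample carrier counts with Bonferroni over regions.

## Cross-technology concordance

Bisulfite-style per-CpG beta values and bin RMS are compared as
unweighted means over 2-kb windows tiled from the start of each merged
target region (the last window of a region may be short). Windows
missing either side are dropped and counted. Pearson correlation is
computed per sample, and the cross-sample average is reported. Window
anchoring and the unweighted (rather than coverage-weighted) beta mean
are deliberate simplifications; correlation is insensitive to affine
rescaling of either side, which the tests verify numerically.

## The synthetic-data generator

`simulateStudy()` emulates the statistical structure the analysis
assumes, not the sequencing process. Its defaults define the reference
desk-scale study, chosen once:

* **Geometry**: 2 chromosomes of 1 Mb; 50 islands of 500–1,500 bp
  placed on the bin grid with even spacing, so the 2-kb shores tile into
  exactly 2,000 100-bp shore bins; 40 genes anchored at islands with
  alternating strand (promoter = the island-adjacent shore); 2 TFBS per
  promoter linked to 5 TFs.
* **Samples**: 10 per subtype. The real panel's per-subtype counts are
  supplementary material we do not ship; 10/10/10 keeps the group sizes
  balanced and configurable.
* **Methylation**: region baselines CpGI 0.15, shore 0.45, shelf 0.6,
  gene body 0.7, intergenic 0.65 — the standard methylome shape
  (hypomethylated islands, intermediate shores, heavily methylated gene
  bodies); truncated-normal noise of sd 0.1 (clamped to [0, 1]; the
  truncated normal gives direct control of effect sizes, which a beta
  distribution would not); an island-boundary peak of +0.2 on the two
  shore bins adjacent to each island end in luminal and basal A only,
  reproducing the boundary-peak-versus-flattened contrast between
  subtypes; and a planted −0.3 shore hypomethylation in basal B on 200
  bins (10 island-adjacent promoter-side shore bins of each of the 20
  coupled genes).
* **Expression**: coupled genes follow baseline 8 − 3 × (promoter TFBS
  RMS) + N(0, 0.3) on a log-intensity-like scale, giving Spearman rho
  well below −0.5 at the planted effect size; uncoupled genes and TF
  genes are subtype-invariant noise, so the TF-similarity filter is
  satisfiable by construction.
* **Mutations**: background CpG sites are scattered over bins; the
  per-observation mutation probability is a step function of the
  sample's bin RMS (step at 0.5), per subtype: basal A is elevated
  (0.03 vs 0.01) below the step and basal B strongly elevated (0.15 vs
  0.05) above it, mirroring the low/intermediate-methylation basal A
  excess and the hypermethylated basal B excess. Planted
  subtype-specific sites (5% of the site count) are carried by 35–60%
  of one subtype and absent elsewhere, with basal A sites restricted to
  CpGI/shore/shelf bins and basal B sites to intron-only bins
  (intron-only, because gene bodies overlap islands and shores in this
  geometry and the intron enrichment would otherwise be confounded).
  Coverage is Poisson(30) capped at 250; mutated observations draw
  mismatches at fraction 0.5 (heterozygous) or ≈1 (homozygous, 20% of
  events); others at the error rate.
* **Validation panel**: per-CpG betas for the first two samples of each
  subtype (a six-sample panel), beta = bin RMS + N(0, 0.05), over the
  gene regions ± 2 kb.

Every stage derives its RNG stream from `seed` plus a fixed offset, so
the whole study is byte-reproducible and each stage is individually
reproducible. What the generator does **not** emulate: read-level
noise and alignment artefacts, copy-number variation, spatially
correlated methylation beyond region means, probe/bin-level biases of
affinity capture (CpG-density dependence of RMS), or realistic linkage
between mutations and expression. Passing tests therefore demonstrate
the correctness and calibration of the statistical machinery under the
assumed data model, not performance on real sequencing data.

## Numerical choices and degenerate inputs

Bonferroni multipliers always count only hypotheses actually tested.
Kruskal–Wallis on a constant row is undefined and reported NA, excluded
from the BH adjustment. Zero-width or off-chromosome profile positions
contribute nothing rather than erroring. The binomial tail is computed
through the standard distribution function and verified in the tests
against an independent exact-summation oracle to 1e-12. Exact mean ties
in the bin test ("tie" direction), empty region classes (NA ratios),
empty strata (NA rates), and TFBS overlapping no bin (excluded,
reported) are all handled explicitly rather than silently coerced.

## Problem sizes used by the test suite

The suite validates the pipeline at sizes chosen to make the
statistical claims sharp while keeping a full run inside a coffee
break: the reference study (20,000 bins × 30 samples), 200 pure-noise
replicates of a 500-bin genome for family-wise error control, 1,000
random vectors for the DMR-merge oracle, the full 11³ carrier-fraction
enumeration for the subtype-specific rule, ramped-methylation mutation
tables with ≥ 2,000 observations per stratum, and 100-replicate
concordance simulations checked against the closed-form attenuation
r = σ²ₛ/√((σ²ₛ+σ²ₐ)(σ²ₛ+σ²ᵦ)).

## Known limitations

Real shore-width conventions vary and the derived shore census depends
on them; the DMR merge rule (adjacency with a gap parameter) is one of
several defensible reductions of bins to regions; the TF-similarity
criterion is a pragmatic operationalisation; and the caller is a
simplified stand-in whose calls should be replaced by a dedicated
variant caller for real pileups. The hypomethylation-ratio and
recovery analyses assume the input RMS is already normalised across
samples — no CNV or capture-efficiency correction is attempted.
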