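---
title: "Models and methods: tissue DMRs, sex-differential methylation and X-scaffold classification"
author: "methylscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`methylscan` re-implements, as tested and reusable components, the
computations of a whole-genome bisulfite sequencing (WGBS) methylome
study in a species with a fragmented assembly and marsupial-style X
chromosome inactivation (XCI): tissue-differential methylated region
(DMR) calling and sharing, GC/length-matched bootstrap enrichment of
DMRs in functional compartments, female-versus-male windowed
methylation contrasts with metagene and TSS profiles, multi-evidence
classification of unplaced scaffolds as X-linked, and integration of
region-level methylation with expression tables. A seeded synthetic
data generator reproduces the statistical structure these analyses
assume and carries machine-readable ground truth, so every stage can be
validated by planted-effect recovery.

# Data model

A `Methylome` is one sample's CpG calls: a width-one `GRanges` with
integer columns `m` (methylated reads) and `u` (unmethylated reads);
fractional methylation is `f = m / (m + u)`. Cytosine reports are
strand-resolved; `mergeStrands()` collapses each CpG dyad to its
forward-strand C, summing counts. A minus-strand call without a covered
partner is still anchored at its dyad's forward C (its own position
minus one), which is what cytosine-report coordinates imply; counts are
conserved exactly either way.

Two record-level filters mirror common practice: `filterMinCoverage()`
(default 3 reads — below that, `f` is mostly noise) and
`filterMinScaffoldLength()` (default 2 Mb — regional statistics need
room). The package merges strands *before* coverage filtering, so a
dyad whose two strands each carry one or two reads can jointly clear
the threshold; the filters themselves are order-agnostic and idempotent,
and the alternative order is a one-line change for users who prefer it.

Annotations use `GRanges` throughout (1-based, closed — the Bioconductor
convention; BED input/output is converted at the boundary by
`rtracklayer`). Promoters are the 1000 bp upstream of the TSS,
strand-aware; gene bodies run TSS to TES; intergenic sequence is the
complement. Where annotations collide, bases are assigned with
precedence gene body > promoter > intergenic, which makes the three-way
partition exact — the test suite asserts it tiles every scaffold with
no gaps or overlaps.

# DMR calling

`smoothTrack()` smooths per-CpG fractional methylation with a
coverage-weighted local polynomial (degree ≤ 2, tricube distance
weights × read coverage). The window around each CpG contains at least
`2 * halfWindowCpgs + 1` CpGs and spans at least `minSpanBp` bases;
defaults (35 CpGs, 1000 bp) follow the documented defaults of
smoothing-based WGBS callers and suit chromosome-scale data. For the
desk-scale synthetic data used in the tests and the pipeline defaults we
use a 4-CpG half-window over at least 200 bp, matched to the ~25 bp CpG
spacing of planted DMR clusters and the ~100 bp background spacing;
these are ordinary bandwidth choices, not magic numbers, and both are
plain arguments.

`callDMRs()` is a two-threshold region caller in the style of
established smoothing-based methods, where the headline "minimum
fractional methylation difference of 0.3 over at least 5 CpGs" is a
*region-level* filter, not a per-CpG one:

1. **Candidates.** Maximal runs of CpGs whose smoothed difference has a
   consistent sign and magnitude ≥ `qualifyDiff` (default `minDiff/2`,
   the half-height of the smallest step the caller targets — the point
   that localises a step edge best), where each CpG's own raw
   difference must not contradict the sign.
2. **Bridging and clustering.** Same-sign runs separated by at most
   `maxGapCpgs = 2` sub-threshold CpGs are joined (one noisy CpG should
   not split a region); regions are split wherever consecutive member
   CpGs lie more than `maxGapBp = 300` apart, the usual CpG-clustering
   rule of region callers.
3. **Edge trimming.** Region ends are trimmed back to CpGs whose raw
   difference itself reaches `minDiff` with the region's sign. Smoothing
   leaks signal into flanking CpGs — especially where a CpG-dense
   region abuts sparse flanks, since the CpG-count window then reaches
   across — and untrimmed calls systematically overshoot their true
   boundaries.
4. **Region filters.** Kept regions need ≥ `minCpgs = 5` members, a raw
   mean difference ≥ `minDiff = 0.3` in absolute value (the raw mean is
   unbiased; the smoothed mean is attenuated at edges), and an evidence
   ratio `|mean| / SE ≥ minZ = 3`, with SE from the per-CpG binomial
   variances — the analogue of the t-statistic cutoff that
   replicate-free smoothing callers use, which keeps regions assembled
   from a few poorly covered CpGs out.

Values exactly at a threshold qualify. With `halfWindowCpgs = 0` and
`qualifyDiff = minDiff` the caller reduces to a single-threshold scan of
raw differences, and the tests verify it then agrees with an
independent brute-force implementation. There is no within-group
variance statistic: the intended study design has one animal per sex,
so regions are called on difference magnitude and read-level evidence
alone. For tissue-versus-tissue comparisons the pipeline pools each
tissue's female and male samples by summing counts — exactly how
group samples enter a pooled smoothing caller — which doubles the
effective coverage per tissue.

Sharing: two DMRs from different tissues are linked when their overlap
is at least 50% of the shorter interval (boundary inclusive; a
reciprocal mode normalising by the longer interval is a flag, since the
convention is not universal). Connected components of the link graph
define shared groups; `tissueConsensusDmrs()` implements the
"differential against every other tissue" definition of a tissue's DMR
set. Clustering of methylomes uses Euclidean distance and Ward
agglomeration on CpGs covered in every sample, with node support from
an ordinary bootstrap over CpG columns — a deliberate, documented
simplification of multiscale bootstrap schemes; at a few hundred
replicates it cleanly separates reproducible from unstable nodes, which
is all the analysis asks of it.

# Matched-control bootstrap enrichment

Whether DMRs concentrate in promoters, gene bodies or intergenic
sequence is tested against length- and GC-matched control regions. Each
of `nBoot` replicates (default 10 000) redraws, for every DMR, one
uniformly sampled interval of identical length whose GC fraction (of
non-N bases) lies within `gcTolerance = 0.05` (absolute) of the DMR's
and which overlaps no excluded region (by default the DMRs themselves).
Fold enrichment is the observed overlap fraction (any-bp rule; a DMR
overlapping two compartments counts in both) divided by the null mean;
the empirical p uses the add-one rule `(1 + #extreme)/(nBoot + 1)` per
tail, doubled and capped at 1, so it can never be exactly zero and is
bounded below by `1/(nBoot + 1)`.

Sampling is uniform over *eligible* positions: per query length the
window-GC track of the whole genome is computed once from cumulative
counts, and draws are vectorised rejection against it (with exact
enumeration as fallback). When no position matches, the tolerance
doubles with a warning, up to five times. Controls are drawn genome-wide
across all retained scaffolds rather than within the query's scaffold —
the natural reading when scaffolds are small — and the exclusion set is
deliberately only the DMRs: on a real genome they occupy a negligible
fraction. On toy genomes that fraction matters; the calibration tests
therefore keep planted DMRs below ~5% of the sequence, since excluding
much more visibly distorts the null.

# Sex-differential methylation

`windowDifferences()` computes, per fixed-size bin (default 10 kb), the
female and male mean fractional methylation over the CpGs covered in
both samples and their difference Δ = f_female − f_male; female
hypomethylation is negative Δ. Distribution-level comparisons
(`compareGroups()`) use the two-sided Mann–Whitney U test, exact when
`n_a * n_b ≤ 400` and tie-free, otherwise the tie-corrected normal
approximation with continuity correction — and the test suite checks
the exact branch against full enumeration.

`metageneProfile()` rescales each gene region 5′→3′ into 20
relative-length bins, averages per gene and bin, then across genes, and
compares female and male *gene-level* values per bin with Mann–Whitney.
Averaging per gene first (rather than pooling CpGs) keeps long genes
from dominating; the alternative pooling convention would weight by CpG
count. `tssProfile()` evaluates 100 bp windows at 10 bp steps across ±5
kb of each TSS, strand-aware, giving exactly 1001 grid points; offsets
with no covered CpG are `NA`, not zero.

`detectCpgIslands()` is the classic sliding-window definition (window
200 bp, GC ≥ 0.5, observed/expected CpG ≥ 0.6, merge-then-revalidate) —
provided because the locus-level analyses need a CGI track, with the
thresholds as arguments. `regionSexDifference()` summarises Δ over the
shared covered CpGs of a set of intervals (e.g. the CpG islands
upstream of an XCI master locus) and reports the relative female
reduction `-meanΔ / mean(f_male)`, the convention under which a female
level of 0.48 against a male 0.75 is a 36% reduction.
`matchedAutosomes()` builds a length-matched autosomal comparison set
by greedy nearest-length selection within ±10%.

# X-linked scaffold classification

Unplaced scaffolds are labelled by `classifyScaffolds()` from three
evidence streams, a reproducible formalisation of what is otherwise a
manual selection step:

* **Hypomethylation shift.** Per tissue, the 10 kb-window Δ values of a
  scaffold are tested for a negative median with the one-sided Wilcoxon
  signed-rank test (exact for ≤ 25 tie-free windows, else
  normal-approximate with continuity correction), and p-values are
  Benjamini–Hochberg adjusted across scaffolds within each tissue.
* **Depth ratio.** Females carry two X copies to the male's one, so the
  female/male median CpG depth ratio sits near 2 on X-derived sequence
  and near 1 on autosomes.
* **Mapped-read proportion** (`mappedReadProportion()`) provides the
  same dosage signal at the mapping level when per-scaffold read counts
  are available.

A scaffold is `X-linked` only when every tissue shows q < 0.05 with a
negative mean Δ *and* the depth ratio falls in [1.5, 2.5] wherever
depth data exist; `autosomal` when no tissue is significant and the
ratio sits in [0.8, 1.2]; anything else is `ambiguous`. Requiring all
tissues is intentionally conservative — dosage and XCI are
tissue-general, so a real X scaffold should not fail in any tissue.
The signed-rank/BH construction is a surrogate for an unstated manual
"significant shift" criterion and is documented as such.

# Methylation–expression integration

`summarizeGeneMethylation()` takes unweighted means of per-CpG `f` over
each gene's promoter and body, with regions under 3 covered CpGs set to
`NA` (which is how poorly covered promoters drop out of correlations).
Associations use Spearman's rank correlation (`rankCorrelation()`,
exact p by enumeration for n ≤ 7 without ties, t-approximation
otherwise). `dmgDegEnrichment()` forms the {DMG, non-DMG} × {DEG,
non-DEG} table over a stated gene universe; fold enrichment is the risk
ratio P(DEG|DMG)/P(DEG|non-DMG) and significance the 1-df chi-squared
test without continuity correction (Yates is a flag; expected counts
are large in intended use). Differential-expression labels are inputs —
from an external caller or the generator's truth — not re-derived here.
`sexExpressionRatio()` is `log2((f + 1)/(m + 1))`, and
`correlateSexdiffMethExpression()` correlates per-gene methylation
Δ(F−M) in a region with that ratio over complete cases, with an
exclusion list for loci (such as the XCI master gene itself) whose
extreme expression asymmetry would otherwise dominate.

# The synthetic data generator

`simConfig()` fixes the study conditions; `generateGenome()`,
`simulateMethylomes()` and `simulateExpression()` (or the
`simulateDataset()` wrapper) produce a complete study deterministically
from one seed. Defaults encode the conditions the analyses target:

* ~10× mean CpG coverage, Poisson per strand, doubled for females on
  X-derived scaffolds (the 2:1 dosage signal);
* per-10 kb-window female−male differences N(−0.25, 0.12) on X gene
  bodies and intergenic sequence, applied as a shared shift per window
  (the classifier tests window-level distributions, so the effect is
  planted at window granularity, not i.i.d. per CpG); promoters get no
  sex effect by default;
* beta/binomial methylation: promoter/CGI CpGs low (Beta(2,8)), gene
  body and intergenic CpGs high (Beta(8,2)), counts binomial in the
  true level — the simplest model matching WGBS marginal behaviour;
* a CpG-depleted background (one CpG per ~100 bp at GC ≈ 0.40) with
  CpG-rich islands planted in promoters;
* tissue-specific DMRs of Δ = 0.4 over 8 CpGs, planted as locally
  CpG-dense clusters (25 bp spacing) on autosomes — DMRs in real
  genomes sit in relatively CpG-dense regulatory sequence, and the
  caller's attainable boundary precision depends directly on local CpG
  density; hypermethylated blocks start from the low archetype so the
  planted shift is not lost to clipping at 1;
* an Rsx-like X locus: two upstream CpG islands whose female
  methylation is reduced by 36% relative to male, and a female-only
  transcript;
* expression with a promoter-methylation coupling targeting Spearman
  ρ ≈ −0.12 (via the Gaussian-copula loading 2·sin(πρ/6)), a mildly
  female-biased baseline (+0.24 log2), a negative gene-body sex
  coupling (slope 1.2 per unit Δ, chosen so the X-versus-autosome log2
  fold-change gap lands near 0.3 and the coupling is clearly detectable
  at a few hundred genes), and planted strongly differential X genes at
  female-up/male-up fractions of 36/209 and 11/209.

What the generator does **not** emulate: read-level artefacts
(alignment error, bisulfite conversion failure, PCR duplicates),
non-CpG methylation, sequence-driven coverage bias, correlated
methylation beyond the window-level X shift, SNPs, and biological
replication (one individual per sex, as in the intended design).
Passing the planted-recovery suite therefore demonstrates the
*statistical machinery* — thresholds, tests, matched sampling,
classification logic — not robustness to upstream artefacts, which
belong to the aligner/caller stages outside this package's scope.

# Numerical choices and problem sizes

Ties and boundaries are inclusive throughout (a difference of exactly
0.3 qualifies; 50% overlap links). Empirical p-values use add-one
smoothing. Exact tests switch to corrected normal approximations
exactly where documented above, and each exact branch has an
enumeration oracle in the tests. Degenerate inputs (all-zero deltas,
constant vectors, empty margins, all-N intervals) return flagged values
or informative errors rather than NaN.

The validation suite runs at desk scale, chosen to make the planted
effects statistically decisive: 30 unplaced scaffolds of 500 kb across
five tissues and twenty seeds for scaffold classification (≥ 95% recall
demanded, zero autosomal false positives); fifty seeds of planted-DMR
recovery scored by base-level Jaccard (≥ 0.8); fifty seeded null and
planted enrichment runs at 200 bootstrap replicates; twenty seeds of
coupling recovery at 2000 and 200 genes. `scripts/acceptance.R`
recomputes the same quantities at reduced replicate counts from a
single command-line seed.

# Limitations

The DMR caller is replicate-free by design and cannot separate
individual from tissue effects; its evidence ratio is a guard, not a
calibrated test. Sharing classification is purely interval-based.
Control matching conditions on GC and length only, not on CpG density
or mappability. The scaffold classifier assumes dosage-driven coverage
and XCI-driven hypomethylation are genome-wide properties of X-derived
sequence; structurally odd scaffolds (pseudoautosomal, highly
repetitive) will land in `ambiguous`. The expression simulator is a
marginal model — it reproduces target correlations and fold-change
structure, not a mechanistic transcription model.
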