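---
title: "Rule-based transcriptome and microRNAome analysis of chilling acclimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based transcriptome and microRNAome analysis of chilling acclimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillseq)
library(dplyr)
```

## The experimental design this package analyses

chillseq implements the computational analysis of a four-condition chilling
experiment on a chilling-sensitive tropical plant such as cassava. One
pooled sequencing library is produced per condition, for mRNA tags and for
small RNAs:

* **NC** — normal control (24°C),
* **CA** — chilling acclimation (24→14°C),
* **CCA** — harsh chilling after acclimation (14→4°C),
* **CS** — chilling shock (24→4°C, no acclimation).

The scientific question is what acclimation changes: which genes respond to
moderate chilling, whether the same genes respond to shock, and — the
headline analysis — how many genes *reverse* their direction of regulation
when an acclimated plant is pushed to the harsh temperature (CA/NC versus
CCA/CA), together with the microRNAs whose expression changes
anti-correlate with their predicted targets.

Because each condition is a single pooled library, there are no replicates
and no dispersion estimate per gene; differential expression is therefore
rule-based rather than test-based. That choice (and its limitations) comes
from the study design, not from this package; packages such as DESeq2 or
edgeR are the right tools when replicates exist.

## Expression and differential-expression rules

Counts are converted to CPM (counts per million mapped reads) using the
per-library mapped totals supplied alongside the table — not the column
sums, since reads can map outside annotated genes. The rules, all
thresholds inclusive/exclusive exactly as stated:

1. **Expressed**: CPM ≥ 10 (`cpm_expressed_min`). Below that the aligned
   reads are treated as noise and the gene's effective expression is 0.
2. **Upper-quartile normalization**: each library's raw counts are divided
   by the 75th percentile of its *nonzero* gene counts. The percentile uses
   R's default linear interpolation (type 7); the cited normalization
   method leaves the interpolation rule open, so it is fixed and documented
   here. After division, values are rescaled by the geometric mean of the
   per-library factors — any positive constant yields identical DE calls
   (the fold rule uses ratios within a gene), the geometric mean simply
   keeps values on a count-like scale.
3. **Differentially expressed** between two conditions when either
   criterion fires:
   * *fold*: expressed in both conditions and the normalized-count ratio is
     ≥ 4 (a ratio of exactly 4.0 is DE);
   * *on/off*: CPM < 10 in one condition and CPM > 40 in the other.

   The fold rule is evaluated on normalized counts, the on/off rule on raw
   CPM — the two rules deliberately use different currencies. A gene
   expressed in neither condition is never DE, whatever the ratio of its
   noise counts. `status` is `up` when the gene is higher in the
   first-named condition of the comparison, so `call_de(profile,
   c("CA", "NC"))` reads "CA relative to NC".

For miRNA count tables no separate thresholds are published; the same
`de_config()` is applied, and every threshold is overridable.

qRT-PCR validation data are handled by `qpcr_relative_expression()`, the
standard 2^−ΔΔCT calculation with a no-template-control rule: a target CT
at or above the NTC CT is reported as not detected.

## Overlap and trajectory (reversal) analysis

`overlap_partition()` compares the up/down gene sets of two contrasts and
partitions their union into common-up, common-down, common-but-opposite,
and contrast-specific genes. Percentages are reported both as shares of
each contrast and as shares of the direction-wise union — published
summaries of this design use both denominators, and the opposite-direction
category is required to make the printed specific/common tallies add up.

`classify_trajectory()` takes the first contrast (CA/NC) and the second
contrast anchored at the first's endpoint (CCA/CA) — not CCA/NC; the
functions take explicit ordered pairs so the wrong anchoring cannot happen
silently. Every gene in the universe (by default the union of DE genes)
gets exactly one class: `reversed`, `continued`, `first_only`,
`second_only`, or `none`. `reversal_summary()` reports, per first-contrast
direction, the count and percentage reversing, continuing, or dropping out.

Printed percentages use one-decimal **round-half-up** (`round_half_up()`),
which matches every checkable published figure; base R's round-half-even
would print 76.25 as 76.2 instead of 76.3.

## miRNA target prediction

Plant miRNAs pair with near-perfect antiparallel complementarity to their
targets, so target prediction is alignment scoring, not seed matching as in
animals. The penalty scheme:

| event | penalty | in seed (miRNA positions 2–7) |
|---|---|---|
| Watson–Crick pair | 0 | 0 |
| G:U wobble (either orientation) | 0.5 | 1.0 |
| other mismatch | 1 | 2 |
| unpaired base (indel) | 1 | 2 |

Position 1 and positions beyond 7 take single penalties — the seed is
strictly positions 2–7. A candidate site is the minimum-penalty global
alignment of the full miRNA against a transcript window, computed by a
layered dynamic programme that tracks the exact number of gaps used, so at
most `max_indels` (default 2) unpaired bases are tolerated per site. The
published description specifies the penalty table but not the alignment
machinery around it; the choices made here are: per-base gap penalties (not
affine), an unpaired miRNA base at position *i* is seed-doubled iff *i* is
in the seed, and an unpaired target base inserted between miRNA positions
*i* and *i+1* is seed-doubled iff *i+1* is in the seed. Sites with total
penalty above `score_cutoff = 4` are discarded (4.0 is retained, 4.5 is
not).

`predict_targets()` scans every transcript offset with window widths within
`max_indels` of the miRNA length (an Rcpp kernel with early termination
once a window provably exceeds the cutoff; `align_site()` is the pure-R
reference implementation with traceback, and the two are cross-checked in
the tests against exhaustive alignment enumeration). Overlapping candidate
windows are merged keeping the best score; ties prefer the window with the
fewest unpaired bases, then the leftmost start — preferring maximal pairing
keeps a planted gap-free site from being displaced by an equal-scoring
shifted variant.

`find_anticorrelated_pairs()` then emits (miRNA, target) pairs where both
members are DE in the same comparison with opposite directions — the
expression signature expected of miRNA-guided repression. One pair is
emitted per (miRNA, transcript) regardless of how many sites the transcript
carries.

## GO enrichment

`enrich()` performs the flat over-representation test: for each term, the
probability of observing at least *k* annotated genes when *m* genes are
drawn from a universe of *M* containing *n* term members — the
hypergeometric upper tail, identical to one-sided Fisher's exact test
(asserted on random tables in the test suite). Implementation is
`stats::phyper` in log space; Benjamini–Hochberg FDR via `stats::p.adjust`
across all tested terms (globally, not per GO namespace). Terms annotated
to fewer than `min_term_size = 2` universe genes are untestworthy and
skipped. No GO-graph ancestor propagation is performed — the test is
term-to-gene as annotated; users who want propagated annotations should
propagate before building the annotation table.

## Read processing at desk scale

Small-RNA reads are qualified in three steps. `trim_adapter()` finds the
longest substring of the 3′ adaptor occurring in the read and truncates at
the leftmost start of that longest occurrence; a read with no adaptor
substring of at least 7 nt ("longer than 6 nt") is considered to have no
adaptor. Truncation repeats until no qualifying substring remains, making
trimming idempotent. `filter_small_rna()` keeps reads with adaptor
evidence, no ambiguous base, and length 17–28 nt; rejected reads are
tallied under their first failing reason. The low-quality rule is not
published; the stand-in used here rejects a read when more than 10% of its
bases fall below Q20 (Phred+33), configurable, and is skipped when no
qualities are present. `count_reads()` assigns qualified reads to
transcripts containing them on the sense strand within one substitution
(the `-v 1` short-read-aligner contract: substitutions only, no indels),
splitting multi-mapped reads fractionally so total assigned mass equals the
number of mapped reads. This counting step is a desk-scale stand-in:
real-scale users align with a genome aligner and supply count tables, which
are the pipeline's primary entry point.

## The synthetic-data generator

`simulate_counts()` generates the statistical structure the analysis
assumes, with planted truth, so every stage is testable without the
original deposited libraries:

* Baseline expression is a heavy-tailed lognormal (meanlog log 6, sdlog 2,
  CPM scale) calibrated so roughly 40% of genes pass the expressed
  threshold at the default depth — matching the published 37–50% expressed
  range.
* Planted classes impose mean ratios of `planted_fold` (default 8) with the
  correct sign pattern across CA/NC, CCA/CA and CS/NC: genes that are DE in
  CA and persist in CCA, genes that revert to baseline in CCA (the
  *reversed* class), a handful that continue further, and CS- or
  CCA-specific genes. Default fractions (0.03 / 0.053 / 0.0005 / 0.03 /
  0.01 of all genes) are the published genome-wide proportions (e.g. 2,855
  DE and 1,801 reversed of 34,151 annotated genes). The CA/NC-then-CCA/CA
  sign structure is planted directly, because that is the quantity the
  trajectory analysis consumes; no temperature dynamics are modelled.
* Planted baselines are direction-dependent: induced (up) genes are drawn
  from the background distribution truncated to 8–40 CPM, so they rise into
  64–320 CPM; repressed (down) genes from the background truncated to
  ≥ 100 CPM, so they fall to ≥ 12.5 CPM. Stress-induced genes being low
  under control conditions is the usual physiology, and this symmetry keeps
  the upper-quartile factors balanced across libraries — planting all DE
  genes at high baselines would make induced and repressed genes
  distort the 75th percentile asymmetrically, a distortion the real
  libraries do not show. It also guarantees each planted effect is
  detectable by at least one DE criterion, so recall measures the caller,
  not the planting.
* Counts are negative-binomial with dispersion 0.05 (variance = μ + 0.05μ²),
  the standard stand-in for biological count noise in an unreplicated
  design; dispersion 0 switches to deterministic `round(μ)` counts, giving
  exact null cases (a fold-1 gene can then never be called DE).
* Library depths default to 2×10⁶ (mRNA) and 5×10⁶ (small RNA) mapped
  reads.
* miRNA tables use the same machinery (150 miRNAs, 33% DE, 20% reversed —
  the published 81 DE and 30 reversed of 154 detected), and each reversed
  miRNA is assigned planted anti-correlated targets among reversed genes of
  the opposite sign.

`simulate_sequences()` embeds target sites constructed by mutating a
miRNA's perfect reverse complement — non-seed wobbles for half-units,
non-seed mismatches for whole units — and verifies each planted site with
`align_site()` at plant time, so the truth table's scores are exact by
construction. `simulate_reads()` produces transcript fragments (17–28 nt in
small-RNA mode) with adaptor prefixes of random length and optional
substitution noise, recording which reads carry ≥ 7 nt of adaptor evidence.

All generators require an explicit seed and are pure functions of
(configuration, seed).

**What passing tests on these data do and do not show.** The generator
reproduces count overdispersion, the planted sign structure, library-depth
scaling, adaptor chimeras and near-perfect complementary sites. It does not
model organ pooling, 3′-tag chemistry biases, GC or length effects,
secondary structure, multi-mapping families of paralogues, or annotation
error. Recovery results on synthetic data therefore validate the *rules and
algorithms*, not the biological accuracy of any particular real-data
result.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full generator defaults
(10,000 genes, 150 miRNAs, four libraries at the default depths) for count
analysis, and a 20-miRNA × 30-transcript × 500-nt transcriptome for the
target scan — sizes chosen so a complete run takes seconds on a laptop
while every code path is exercised at realistic parameter values. Oracle
equivalence for the alignment DP is checked on hundreds of short random
guide/window pairs (an exhaustive enumeration oracle is exponential in
sequence length, so the property is verified where enumeration is
tractable; the DP itself is length-independent). `align_site()` accepts
guides shorter than the 17–26 nt range that `predict_targets()` enforces,
precisely to allow such small-instance verification.

Ties in the DP traceback prefer pairing over gaps (diagonal moves first),
so reported alignments are maximally paired among equal-score options.
Percentage rounding is half-up everywhere a summary is printed; exact
values are kept in the objects themselves. Degenerate inputs are errors,
not silent results: all-zero libraries cannot be upper-quartile normalized,
empty gene sets cannot be enrichment-tested, and count tables must come
with positive mapped totals.

## Known limitations

* The DE rules have no error control; with single pooled libraries that is
  inherent to the design they serve.
* The target-site scan reports one merged site per overlap cluster; two
  genuinely adjacent overlapping sites would be collapsed.
* Whether the original tag counting matched sense-only or both strands is
  not published; counting here is sense-only (cDNA matching), and the
  maximum indel count per target site (2) is likewise this package's
  documented choice.
* GO enrichment treats annotations as flat; without ancestor propagation,
  enrichment of specific terms does not propagate to their parents.
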