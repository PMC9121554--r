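---
title: "From differential chromatin accessibility to regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From differential chromatin accessibility to regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacreg)
```

## The analysis this package implements

ATAC-seq maps open chromatin as peak intervals.  When two conditions — for
example an oncohistone-mutant glioma line and its isogenic wild-type
revertant — are assayed in biological replicate, the scientific questions
are: which regions are accessible in only one condition; where do those
condition-specific regions fall relative to genes; are they concordant with
increased expression of the genes they touch; do they coincide with active
enhancers and super-enhancers; which transcription-factor binding motifs
are over-represented in them; and which TF-to-target-gene network do those
motifs imply.  `atacreg` implements that chain of analyses as small,
separately testable steps, plus a synthetic-data generator that produces
complete inputs with known ground truth, so every step and the end-to-end
pipeline can be validated without any external sequencing data.

All intervals are 0-based half-open (the BED dialect) everywhere inside the
package; 1-based coordinates appear only in the conversion to `GRanges`,
which backs the overlap engine.  Strand is carried but ignored by overlap
operations — ATAC peaks are unstranded — and matters only for promoter
windows, regulatory domains and motif scanning.

## Condition-unique peaks

Two notions of "condition-specific" are provided, because presence/absence
reasoning over replicate peak sets and count-based testing answer slightly
different questions.

**Occupancy mode** (default): the merged union of all per-sample peak sets
is partitioned; a union interval is *unique to A* when every A replicate
contributes an overlapping (>= 1 bp) peak and no B replicate does.  This
mirrors Venn-style reasoning over duplicates and requires no counts.  The
>= 1 bp overlap rule is the bedtools default; no overlap fraction is
imposed (an explicit `min_overlap` is exposed on `intersect_sets()`).

**Affinity mode**: consensus peaks are tested for differential counts.
Counts are normalized with median-of-ratios size factors (geometric-mean
reference over peaks with all-nonzero counts, total-count fallback
otherwise).  A single negative-binomial dispersion
(`variance = mu + alpha * mu^2`) is estimated across all peaks by method of
moments on the normalized counts and then treated as known in a per-peak
two-sided likelihood-ratio test of equal means (chi-squared, 1 df), with
size factors as multiplicative offsets and Benjamini–Hochberg q-values.

One estimator detail matters at typical replicate numbers.  The naive
pooled moment estimator `sum(v - m) / sum(m^2)` over per-group means `m`
and variances `v` is biased *downward*, because `E[m^2] = mu^2 + var/n`;
with two replicates per group the bias is large enough to make the LRT
visibly anticonservative.  `estimate_dispersion()` therefore uses the
unbiased second moment `m^2 - v/n` in the denominator.  With 2 vs 2
replicates and NB counts at mean 100, dispersion 0.1, the null rejection
rate at p < 0.05 sits near 0.05 (the chi-squared approximation itself
contributes a residual ~0.002–0.005 excess at four observations, which we
accept rather than abandoning the standard reference distribution).  The
log2 fold change is `log2((mean_a + 0.5)/(mean_b + 0.5))` — the 0.5
pseudocount keeps it finite for empty peaks.  Setting the `dispersion`
argument near zero reproduces a Poisson likelihood-ratio test, which the
test suite uses as an independent limit check.

## Annotation and gene linkage

Promoters are the strand-aware window from 2 kb upstream to 1 kb
downstream of the TSS (both configurable).  The TSS is the body start on
`+` and the last base (`end - 1`) on `-`; one model per `gene_id` is
required, with an explicit helper that collapses duplicates to the longest
body.  Peaks are classified peak-wise (not base-wise) into
promoter > exon > intron > intergenic by >= 1 bp overlap; precedence
resolves multi-feature peaks, promoter first, so the reported promoter
fraction is conservative with respect to the other categories.  The four
categories partition any peak set and their fractions sum to 1.

Peak-to-gene links use the full transcript span; concordant genes are those
with `padj` below the threshold, fold change in the requested direction,
and at least one linked condition-specific peak.

Enhancers are H3K27ac intervals minus promoter windows.  Region-to-gene
association follows the basal-plus-extension convention: a basal domain of
5 kb upstream / 1 kb downstream of the TSS, extended in each direction by
up to 1 Mb but never into a neighbouring gene's basal domain.  The 5 kb /
1 kb / 1 Mb defaults are the convention of the tool this rule emulates;
all three are configurable.  Super-enhancer hits are super-enhancers
containing at least one condition-unique peak, annotated with associated
genes and their upregulation status; a catalog's own SE-to-gene table can
override the rule per super-enhancer.

## Motif statistics

Motifs are position probability matrices with a pseudocount (default 1e-3)
and a background model (default uniform).  A k-mer scores
`sum_i log2(p_i(b_i)/bg(b_i))` bits.  The p-value of a score is the exact
probability that a background-drawn k-mer scores at least as high, computed
by dynamic programming over a discretised score lattice with bin width
1e-3 bits.  The lattice threshold uses a half-window rule
(`ceil(score/delta - width/2)`): every k-mer whose true score reaches the
query is guaranteed to be counted, p-values are monotone non-increasing in
the score, and they agree *exactly* with exhaustive enumeration whenever
distinct achievable scores are separated by more than `width * delta`
bits — which the shipped fixture matrices guarantee by construction, and
which the suite verifies against full 4^w enumeration at widths <= 6.

Scanning slides the motif over both strands (reverse strand scored on the
reverse complement), reports all positions below the p-value threshold,
counts overlapping hits without masking, and skips windows containing
ambiguous bases.  A caveat inherited from all scanners of this kind: a
width-w motif's best achievable p-value is `4^-w` under a uniform
background, so a width-6 motif can never pass a 1e-4 threshold; the
default threshold is 1e-4, and short-motif analyses should relax it
deliberately.

Background enrichment follows the scramble recipe: each sequence is
permuted uniformly at random (mononucleotide shuffle, composition exactly
preserved), the scan is repeated over `n_shuffles` (default 10)
independent scrambles, and
`fold = observed / max(background_mean, 0.5/n_shuffles)` — the floor
prevents an infinite ratio when no background hit occurs.  A motif is
called enriched at fold >= 2, the threshold used in the analyses this
package reproduces.  Dinucleotide-preserving shuffling is deliberately not
the default: the generator's genomes are i.i.d. uniform, so mononucleotide
scrambling is the matched null; on real sequence, CpG and repeat structure
make the mononucleotide null anticonservative for some motifs (see
Limitations).

A calibration note: the fold statistic is a ratio of two small counts.
For it to sit reliably inside a fixed multiplicative band such as
[0.5, 2) under the null, the expected hit count must be large (~100+).
Because achievable p-values of short motifs are coarse, the null
calibration checks in the test suite scan at a permissive threshold
(0.05, expected ~150 hits on 2 kb of sequence) where the band holds in
essentially every trial; at a strict threshold the expected count is ~18
and Poisson noise alone breaches the band in several percent of trials.

## Gene-set enrichment and the network

Over-representation uses the exact hypergeometric upper tail (`P(X >= k)`)
per term with Benjamini–Hochberg correction applied separately within each
category (BP, CC, MF, KEGG, other), matching per-category reporting
conventions; a pooled mode exists.  The universe defaults to all genes in
the supplied gene table — the analyses being emulated do not state their
background, and the choice materially affects p-values, so the universe
size is attached to every result.  The plain hypergeometric is used rather
than the EASE-adjusted variant some GO servers apply.

The regulatory network connects each *enriched* motif (fold >= 2) to the
concordantly upregulated genes that have at least one linked
condition-specific peak carrying a hit of that motif.  Edges collapse
multiple supporting peaks, retaining the peak count and per-hit evidence;
heterodimer motif identifiers are single TF nodes; hub TFs are reported by
out-degree ranking only — no statistical test is attached, since none is
defined for this construction.  Exports: GraphML (igraph), SIF, and
node/edge TSVs.

## The synthetic-data generator

The generator emulates the study design the pipeline targets: two isogenic
conditions in biological duplicate, shared plus condition-unique peaks, NB
fragment counts, motif instances implanted into condition-A-unique peaks,
an expression table whose upregulated genes host a configurable fraction
of the unique peaks, and H3K27ac/super-enhancer tracks built around
coupled peaks.  Defaults: 2 chromosomes x 3 Mb of i.i.d. uniform sequence,
150 genes (3–8 kb, 2–4 exons), 200 shared and 50 unique peaks per
condition at 300–700 bp, NB mean 100 and dispersion 0.1 for open peaks
versus mean 5 closed, implant rate 0.5, coupled fraction 0.6, log2FC of
upregulated genes from a positive-truncated Normal(2, 0.5).  Where the
emulated study reports no value (it publishes no library depths or effect
sizes), these are chosen once for testability at desk scale, not fidelity
to any particular cell line.

Geometry is chosen so features cannot interact by accident: genes are
placed with a 7 kb margin (no promoter window or basal domain reaches into
a neighbouring gene's body), peaks with a 1.5 kb margin (±500 bp H3K27ac
padding can never stitch unrelated peaks into a super-enhancer, given the
1 kb stitch gap).  Coupled unique peaks are placed inside the bodies of
their target genes, one per gene; uncoupled peaks go to intergenic space.
The configuration validates total placement capacity up front and placement
errors name the violated capacity.

All randomness flows from one integer seed through fixed per-stage child
seeds (`genome`, `genes`, `peaks`, `counts`, `implant`, `expression`,
`h3k27ac`), so each stage is independently reproducible and a seed
reproduces byte-identical output files.

What the generator does *not* emulate — and what green tests therefore do
not show about real data: sequence composition structure (CpG islands,
repeats, dinucleotide bias) that shapes real motif backgrounds; peak-width
and signal heterogeneity; replicate-specific peak-call noise (replicates
share identical true intervals, so occupancy recovery is exact by
construction and its test is a plumbing check, not a sensitivity result);
fragment-level artefacts (no reads are simulated); and isoform complexity
(one transcript per gene).

## Problem sizes and numerical choices

The shipped tests run the oracle comparisons at 1,000 intervals per set,
PWM enumeration at widths <= 6 (4,096-65,536 k-mers), the differential
null at 2,000 peaks x 4 samples, motif calibration at 100 seeded trials of
2 kb each, and the end-to-end recovery at the default generator scale (300
true peaks, 150 genes, 6 Mb) — sizes at which every check completes on a
single CPU in seconds while leaving the statistics enough resolution to
fail informatively.  Ties and degenerate inputs are handled explicitly:
empty interval sets propagate as empty results (never errors) except where
a result would be meaningless (annotating zero peaks, enriching against an
empty universe); all-zero count rows trigger the total-count normalization
fallback with a message; a PWM wider than its peak is skipped with a
warning and recorded as unimplanted.

## Known limitations

Occupancy calls inherit the peak caller's binary view: a region weakly
open in both conditions but called in only one is "unique".  The common-
dispersion NB test has no trended or tagwise dispersion and no GLM design
beyond two groups.  GREAT's binomial genomic-fraction test is not
implemented; gene-based hypergeometric enrichment replaces it.  Motif
enrichment is count-based (fold over scrambles) without a positional or
footprint model, and no de novo motif discovery is attempted — the PWM
library is an input.
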