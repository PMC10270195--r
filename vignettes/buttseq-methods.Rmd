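---
title: "Methods: nascent 3'-end profiling analysis with buttseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nascent 3'-end profiling analysis with buttseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buttseq)
```

## The measurement model

Nascent-RNA 3'-end sequencing (Butt-seq and related protocols such as
3NT-seq and NET-seq) reads out the last base synthesized by RNA
polymerase II: the 3' end of a chromatin-associated transcript marks the
polymerase's current position. After alignment, each properly paired
read is truncated to the first base sequenced by read 2, giving a
sparse, stranded, single-nucleotide count map — the central analyte of
this package (`snt_signal`). Two features of such libraries shape every
downstream step:

* **Promoter-proximal pausing.** A large share of polymerase sits
  20–120 bp downstream of the TSS, producing a sharp single-base peak
  against a low uniform elongation background.
* **Contamination.** Mature small RNAs (snoRNA/snRNA/scaRNA), rRNA, and
  the 3' ends of spliced exons co-purify with chromatin and must be
  masked before any pausing statistic is computed.

### Coordinate and strand conventions

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
and SAM (1-based) are converted at the parsing boundary, BED and
bedGraph pass through unchanged. A minus-strand gene's TSS is `end - 1`
and every window is mirrored, so "downstream" always means the direction
of transcription.

Read 2 is taken to be antisense to the nascent RNA (`read2_sense =
FALSE` by default): the reverse-transcription primer sits at the RNA 3'
end, so read 2's first sequenced base is the 3'-most templated base and
its alignment extends toward the RNA 5' end. Under this geometry the
reported signal strand is the opposite of the read-2 mapping strand. For
libraries built the other way around, `read2_sense = TRUE` flips the
convention; nothing else changes.

### UMI deduplication

Duplicates are collapsed on the exact key *(chromosome, strand, read-1
5' position, read-2 5' position, UMI)*, keeping the first record seen.
Exact-key grouping is deterministic and exactly testable against the
generator's truth; no UMI-error network (directional collapsing) is
built, which slightly undercollapses in the presence of sequencing
errors in the UMI — the generator does not model those, and real
libraries with error-prone UMIs should be collapsed upstream if that
matters. Soft-clipped bases never consume reference, so clip removal
only zeroes bookkeeping fields; the single-nucleotide anchor is always
the first *aligned* base of read 2 in sequencing order.

## Pause detection

Candidate positions are single bases with count ≥ `min_intensity`
(default 5) inside the first `search_region` nt (default 200)
downstream of a TSS; overlapping same-strand TSS windows are merged and
a called position is attributed to every member gene whose own window
contains it. For each candidate with count *c*, a window of
`window` positions (default 100) is centered on it and clipped at the
search-region boundary. The null model drops the window's total *T*
reads i.i.d. uniformly over its *W* positions; the test statistic is
the maximum single-position count of a resample, and

$$p = \frac{1 + \#\{\text{resamples with max} \ge c\}}{n_{boot} + 1}.$$

Three numerical details matter:

* **Add-one correction and the analytic fallback.** With the default
  10,000 resamples the smallest reportable bootstrap p-value is
  1/10,001 ≈ 1e-4, which can never pass the 1e-5 emission threshold.
  Whenever the exceedance count is zero we therefore report the
  Bonferroni (union-bound) tail of the multinomial maximum,
  $\min\!\big(W \cdot P(\mathrm{Bin}(T, 1/W) \ge c),\ 1/(n_{boot}+1)\big)$,
  an upper bound on the true p capped at the bootstrap floor. Tests
  verify the bootstrap against full multinomial enumeration for small
  (*T*, *W*).
* **A sound pre-screen.** $P(\max \ge c) \ge P(X_{pos} \ge c)$ for any
  fixed position, so candidates whose single-position binomial tail
  already exceeds the threshold are skipped without resampling. This is
  exact, not an approximation, and makes dense uniform backgrounds
  cheap.
* **Determinism.** One seed drives all resampling; null maxima are
  cached per (*T*, *W*) within a run, so identical inputs give
  identical calls.

When a gene carries several calls, the one with the highest count wins;
ties go to the most TSS-proximal site (deterministic and biologically
conservative, since pausing concentrates near the TSS). "Highest count"
rather than "lowest p" was chosen because counts are the biologically
interpretable quantity and p-values saturate at the analytic bound for
strong peaks.

Motifs are summarized as a position frequency matrix over
strand-corrected sequences ±10 nt around the pause base. The synthetic
genome plants an initiator-like bias (G/A at −1, T/C at +1 on the coding
strand) so motif recovery is testable end to end.

## Pausing indices and comparison

Two definitions are provided:

* **Anchored**: pause region = TSS to the highest pause (inclusive);
  body = the 1000 bp immediately downstream of the pause. 1000 bp is
  the default; 2000 bp is a common alternative and is exposed as
  `body_length` — analyses should state which they used.
* **Fixed**: promoter = −50/+200 around the TSS; body = the rest of
  the gene.

Both use **length-normalized densities** (signal per bp) so that
variable-length pause regions are comparable across genes and between
the two definitions; `raw_ratio = TRUE` gives the plain signal ratio.
Genes with zero body signal are flagged and excluded from ECDFs rather
than producing infinities. Density ratios are invariant to global
library scaling, which is verified exactly in tests.

Cohorts are compared on the ECDF of log2 indices with the two-sample
Kolmogorov–Smirnov statistic (exact D on pooled points, asymptotic
p-value), and condition-versus-condition pause movement is summarized
as the median signed offset difference (negative = toward the TSS, the
signature of superelongation-complex inhibition).

Library-size normalization uses the median-of-ratios method over
counts at regions of interest (merged TSS windows by default): the
reference is the per-feature geometric mean across samples, features
with any zero are excluded from the reference set, and each sample's
factor is the median ratio to the reference.

## Metagene profiles

TSS-anchored matrices use 1-bp bins, 200 bp upstream to 1000 bp
downstream, genes ≥ 5 kb by default; scale-region mode linearly rescales
bodies to a fixed number of bins. Rows are ranked by total signal and
`ceiling(0.001 N)` rows are trimmed from each tail — the ranking
statistic (row total) is a documented choice, since per-column trimming
is the other defensible reading. A pseudocount of 1 is added, values
are log2-transformed, and a percentile bootstrap over row resampling
(default 10,000 resamples) gives 95% bands. Percentile (not BCa)
intervals are used; coverage is verified by simulation to sit near the
nominal level (~93–96% at 200 rows).

## Subnucleosomal MNase analysis

Fragments are filtered to 58 ± 5 bp, the footprint of one half of a
partially unwrapped histone dyad. Midpoints are smoothed with a
Gaussian kernel (SD 15 bp); local maxima supported by ≥ 10 raw
midpoints within ±10 bp become dyad half-peaks, and two half-peaks
40–80 bp apart are paired into a nucleosome whose center is their
rounded mean (the two halves sit ±29 bp from the dyad axis). A lone
half-peak yields an unpaired call that is interpreted as the surviving,
TSS-proximal half with zero distal mass — the state of a nucleosome
whose distal contact has been fully lost. The upstream literature's
exact center-calling procedure is not specified at this level of
detail, so this kernel/pairing scheme is this package's documented
stand-in, with every parameter exposed.

A call is a **−1 nucleosome** when its canonical 147-bp footprint
`[center − 73, center + 74)` covers an annotated TSS (the canonical
width is a choice; the subnucleosomal footprint itself is 58 bp).
Pause–center distances are signed downstream-positive along the gene
strand and stratified into the five standard bins (80–120, 60–79,
40–59, 20–39, 0–19 bp); distances outside [0, 120] stay unassigned.

## Two-condition concordance and circadian quantification

For two conditions sharing merged pause anchors (larger pooled count
wins; ties TSS-proximal), pause and elongation regions are quantified,
normalized, and classified by a symmetric fold-change rule (default
2×) with a minimum-count filter (default 10). The resulting 3×3 grid
yields concordant / single-discordant / double-discordant fractions.
The threshold is necessarily a convention — the field reports such
grids without stating a decision rule — so the package exposes it and
reports it in the output rather than pretending a canonical value
exists; published percentage splits from real tissue pairs should not
be expected to reproduce under any particular threshold.

Circadian time courses are quantified as strand-matched **exon-only**
sums per gene per timepoint (intronic signal from co-transcriptional
splicing intermediates is excluded by construction), median-of-ratios
normalized across timepoints, then optionally row-normalized to each
gene's peak timepoint. Peak/trough calls are simple argmax/argmin with
an infinity flag for zero troughs.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions:

* Genes (1–3 exons, first transcribed exon ≥ 400 bp so the pausing
  region never touches a masked exon 3' end) are placed with ≥ 2 kb
  intergenic gaps; each gene gets one true pause 20–120 bp downstream
  of the TSS, a −1 nucleosome center 0–120 bp upstream of the pause,
  and circadian parameters.
* A molecule is a pause read with probability `pause_fraction`
  (default 0.3), otherwise uniform over the body downstream of the
  pause; contaminant molecules end inside small-RNA/rRNA loci. Each
  molecule carries a random 8-bp UMI and is emitted
  `1 + Poisson(pcr_duplication_rate)` times with identical coordinates
  and UMI — PCR duplicates are exact copies, matching the exact-key
  dedup contract. Two distinct molecules that coincide in every
  observable (both mate 5' ends, strand, UMI) are collapsed in the
  truth table, because no method can distinguish them from duplicates;
  with 8-bp UMIs and hundreds of reads per position such collisions are
  expected and are not an error of the pipeline.
* MNase fragments (58 ± 5 bp) center on one dyad half; the proximal
  half has weight 1 and the distal half `1 − dyad_loss`, so the
  distal/proximal mass ratio equals `1 − dyad_loss` exactly.
* Time courses draw per-gene exonic counts from
  `Poisson(baseline · (1 + A cos(2π(t − φ)/24)))` with φ = ZT14 and
  A = 0.9 for the rhythmic cohort (default 40% of genes; the
  non-rhythmic majority anchors cross-timepoint normalization, as in
  real tissue, where median-of-ratios would otherwise absorb a
  synchronized oscillation). A constant low-rate intronic background is
  added. Constitutive-pause genes (a subset of the rhythmic cohort)
  keep a constant pause-site intensity while their body cycles — the
  signature of pause-release–regulated clock genes.

What the generator does **not** model, and what passing tests therefore
do not establish for real data: sequencing errors (including in UMIs),
alignment ambiguity and multimapping, fragment-length and GC bias,
template-switching artifacts, overlapping gene architecture beyond
shared TSS windows, transcription past the TES, and pause sites outside
the configured offset window. Defaults for quantities the field does
not pin down (pause strength, expression dispersion, duplication rate)
were set once to values a practitioner would call realistic and are all
exposed in `sim_config()`.

## Problem sizes and determinism

The shipped tests run the pipeline at the scales the analyses are
designed for while staying fast: 200-gene genomes with 10^5 molecules
for pipeline exactness, 200 paused plus 200 pause-free genes for
recovery/specificity, 320 genes for the pause-shift phenotype, 10^5
bootstrap resamples against full multinomial enumeration, 200
replicates for confidence-interval coverage, and ~40,000 MNase
fragments for dyad recovery. Every stochastic step takes an explicit
seed and is bit-reproducible; `run_demo()` chains the whole pipeline
from one root seed.

## Known limitations

* The bootstrap null assumes uniform elongation within a window;
  structured backgrounds (e.g. pausing zones with elevated local rates)
  make the test anti-conservative near strong gradients.
* The exact-mode dedup treats UMI sequencing errors as distinct
  molecules.
* The concordance decision rule and the nucleosome center-caller are
  documented conventions, not reimplementations of any particular
  published internal procedure.
* KS p-values are asymptotic; for very small cohorts use the D
  statistic directly.
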