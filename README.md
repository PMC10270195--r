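# buttseq

Downstream analysis of nascent-RNA 3′-end sequencing (Butt-seq–style)
data in R. The 3′ end of a chromatin-associated transcript marks the
base RNA polymerase II synthesized last, so sequencing nascent 3′ ends
at single-nucleotide resolution reads out polymerase positions
genome-wide — most prominently the sharp promoter-proximal pause
20–120 bp downstream of the TSS. This package takes aligned paired-end
reads from such libraries through the full analysis:

* **Preprocessing** — UMI deduplication on the exact key
  *(chrom, strand, r1 5′, r2 5′, UMI)*, soft-clip handling, truncation
  of each pair to the first aligned base of read 2, and masking of
  small-RNA and exon-3′-end contaminant positions, with a QC report.
* **Pause detection** — for a candidate base with count *c* in a
  100-bp window holding *T* reads over *W* positions, a bootstrap
  uniform-multinomial null on the window maximum:
  *p* = (1 + #{resamples with max ≥ *c*}) / (*n*<sub>boot</sub> + 1),
  with an analytic Bonferroni tail
  *W*·P(Bin(*T*, 1/*W*) ≥ *c*) replacing the add-one floor when no
  resample reaches *c*. Defaults: window 100, minimum intensity 5,
  10,000 bootstraps, *p* ≤ 10⁻⁵, 200-nt TSS search region; one
  (highest) pause per gene; ±10-nt motif matrices.
* **Pausing metrics** — pause-anchored index
  (TSS→pause density ÷ 1000-bp body density) and fixed-window
  (−50/+200) index, ECDF/Kolmogorov–Smirnov comparison, and
  median-of-ratios size factors.
* **Metagene profiles** — 1-bp TSS-anchored or scaled matrices, 0.1%
  tail trimming, log2(x+1), percentile-bootstrap 95% bands
  (10,000 resamples).
* **Chromatin** — 58 ± 5 bp subnucleosomal MNase fragments, dyad-half
  pairing into nucleosome centers, −1 (TSS-overlapping) nucleosome
  calls, and pause–nucleosome distance clusters
  (80–120 / 60–79 / 40–59 / 20–39 / 0–19 bp).
* **Comparative** — merged pause anchors across two conditions,
  pause/body fold-change concordance grids, and circadian exon-only
  time-course quantification with peak normalization.
* **Synthetic data** — a ground-truthed generator (genomes, reads with
  8-bp UMIs and PCR duplicates, contaminants, MNase dyads, sinusoidal
  six-timepoint transcription) that makes every step exactly testable.

Standard formats are supported throughout: SAM text, GTF, BED,
bedGraph, FASTA, chrom.sizes.

## Worked example

`run_demo()` chains the whole pipeline on synthetic data from one seed:

```r
library(buttseq)
res <- run_demo(outdir = "demo_out", seed = 42)

str(res$qc)
#> $ input_pairs       : int 10523
#> $ kept              : int 5333
#> $ duplicates_removed: int 5190
#> $ small_rna_fraction: num 0.0482
#> $ rrna_fraction     : num 0.0531
#> $ masked_signal     : num 257

head(res$pauses[, c("gene_id", "position", "count", "p_value",
                    "offset_from_tss")], 3)
#>    gene_id position count   p_value offset_from_tss
#> 1  gene001     2047    25 1.000e-48              47
#> 45 gene002     9789    17 1.783e-31              21
#> 13 gene003    18402    28 1.000e-54              50

median(log2(res$indices$index[res$indices$ok]))
#> [1] 5.51
```

Reading the output: of 10,523 input pairs, 5,333 unique molecules
survive exact-key UMI deduplication (the simulation uses a PCR
duplication rate of 1, so roughly half the pairs are copies); ~4.8% of
the 3′-end signal falls in small-RNA loci and is masked along with exon
3′ ends (257 positions' worth). Every one of the 60 simulated genes
yields a pause call at its true base — e.g. `gene001` pauses 47 nt
downstream of its TSS with 25 reads, far beyond what a uniform window
would produce (p ≈ 10⁻⁴⁸, here the analytic tail bound). The median
log2 anchored pausing index of ≈ 5.5 says pause-region signal density
is ~45× body density, as configured. The output directory also
carries stranded bedGraphs, a pause BED/TSV, the metagene summary, a
two-condition concordance grid, and a peak-normalized six-timepoint
(ZT2–ZT22) table in which rhythmic genes peak at ZT14.

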