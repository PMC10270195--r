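#' Strip soft clips from read 2
#'
#' Soft-clipped bases are unaligned by definition and never consume
#' reference, so the aligned span is unchanged; this records that the
#' "first sequenced base" anchor is the aligned end adjacent to the 5'
#' soft clip, zeroes the clip fields, and sets the `clips_stripped` flag.
#' Pairs whose read 2 has no aligned bases are dropped with a warning.
#'
#' @param pairs An `aligned_pairs` table.
#' @return The table with clip fields zeroed and flag set.
#' @export
strip_softclips <- function(pairs) {
  out <- data.table::copy(pairs)
  degenerate <- out$r2_end <= out$r2_start
  if (any(degenerate)) {
    warning(sprintf("dropping %d fully clipped/empty read 2 alignment(s)",
                    sum(degenerate)))
    out <- out[!degenerate]
  }
  out[, r2_leading_softclip := 0L]
  out[, r2_trailing_softclip := 0L]
  out[, clips_stripped := TRUE]
  class(out) <- class(pairs)
  out
}

#' Deduplicate pairs by UMI and mate positions
#'
#' Exact-key grouping on (chrom, strand, read-1 5' position, read-2 5'
#' position, UMI): one representative per key, the first encountered.
#' This is deterministic exact-mode collapsing; no UMI-error network is
#' built.
#'
#' @param pairs An `aligned_pairs` table.
#' @param verbose Log kept/removed counts (default TRUE).
#' @return List with `pairs` (deduplicated), `kept`, `removed`.
#' @export
deduplicate <- function(pairs, verbose = TRUE) {
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, kept = 0L, removed = 0L))
  r1_5p <- ifelse(pairs$r1_strand == "+", pairs$r1_start, pairs$r1_end - 1L)
  r2_5p <- ifelse(pairs$r2_strand == "+", pairs$r2_start, pairs$r2_end - 1L)
  key <- paste(pairs$chrom, pairs$r2_strand, r1_5p, r2_5p, pairs$umi,
               sep = "\r")
  keep <- !duplicated(key)
  out <- pairs[keep]
  class(out) <- class(pairs)
  if (verbose)
    message(sprintf("deduplicate: kept %d, removed %d duplicate(s)",
                    sum(keep), sum(!keep)))
  list(pairs = out, kept = sum(keep), removed = sum(!keep))
}

#' Convert pairs to single-nucleotide 3'-end positions
#'
#' Each pair is truncated to the first aligned base of read 2 in
#' sequencing order: `r2_start` when read 2 maps to `+`, `r2_end - 1`
#' when it maps to `-`. The reported strand is the strand of the nascent
#' RNA; by default read 2 is antisense to the RNA (`read2_sense = FALSE`),
#' so the signal strand is the opposite of the read-2 mapping strand.
#'
#' @param pairs An `aligned_pairs` table (deduplicated, clips handled).
#' @param read2_sense If TRUE, read 2 maps on the nascent-RNA strand.
#' @return An [snt_signal()] of per-position counts.
#' @export
to_single_nucleotide <- function(pairs, read2_sense = FALSE) {
  if (nrow(pairs) == 0L) return(snt_signal())
  pos <- ifelse(pairs$r2_strand == "+", pairs$r2_start, pairs$r2_end - 1L)
  rna_strand <- if (read2_sense) pairs$r2_strand else
    ifelse(pairs$r2_strand == "+", "-", "+")
  snt_signal(chrom = pairs$chrom, strand = rna_strand, pos = pos,
             count = rep(1, nrow(pairs)))
}

#' Mask contaminant positions from a signal
#'
#' Deletes positions overlapping any small-RNA or exon-3'-end interval
#' (strand-matched; half-open boundaries). The amount of removed signal
#' is logged.
#'
#' @param signal An [snt_signal()] object.
#' @param ann An [annotation_set()].
#' @param verbose Log removed signal (default TRUE).
#' @return The masked `snt_signal`.
#' @export
mask_contaminants <- function(signal, ann, verbose = TRUE) {
  mask <- rbind(ann$small_rna[, c("chrom", "start", "end", "strand")],
                ann$exon_three_prime_ends[, c("chrom", "start", "end", "strand")])
  if (nrow(mask) == 0L || nrow(signal) == 0L) return(signal)
  hit <- overlaps_positions(signal, mask, stranded = TRUE)
  if (verbose)
    message(sprintf("mask_contaminants: removed %.0f of %.0f signal (%.1f%%)",
                    sum(signal$count[hit]), sum(signal$count),
                    100 * sum(signal$count[hit]) / max(sum(signal$count), 1)))
  out <- signal[!hit]
  class(out) <- class(signal)
  out
}

#' Contamination report
#'
#' Fractions of total (pre-mask) signal overlapping small-RNA and rRNA
#' intervals, strand-matched.
#'
#' @param signal An [snt_signal()] before masking.
#' @param ann An [annotation_set()] with `small_rna` and `rrna`.
#' @return List with `small_rna_fraction` and `rrna_fraction` in \[0, 1\].
#' @export
contamination_report <- function(signal, ann) {
  tot <- total_signal(signal)
  if (tot == 0) return(list(small_rna_fraction = 0, rrna_fraction = 0))
  sm <- overlaps_positions(signal, ann$small_rna, stranded = TRUE)
  rr <- overlaps_positions(signal, ann$rrna, stranded = TRUE)
  list(small_rna_fraction = sum(signal$count[sm]) / tot,
       rrna_fraction = sum(signal$count[rr]) / tot)
}

#' Full preprocessing: pairs to masked single-nucleotide signal
#'
#' Strip soft clips, deduplicate, convert to 3'-end positions, report
#' contamination, and mask small-RNA/exon-3'-end positions.
#'
#' @param pairs An `aligned_pairs` table.
#' @param ann An [annotation_set()].
#' @param read2_sense Passed to [to_single_nucleotide()].
#' @param verbose Log filter counts.
#' @return List: `signal` (masked), `signal_unmasked`, `qc` (kept,
#'   removed duplicates, contamination fractions, masked signal).
#' @export
preprocess_pairs <- function(pairs, ann, read2_sense = FALSE,
                             verbose = TRUE) {
  stripped <- strip_softclips(pairs)
  dd <- deduplicate(stripped, verbose = verbose)
  sig <- to_single_nucleotide(dd$pairs, read2_sense = read2_sense)
  rep <- contamination_report(sig, ann)
  masked <- mask_contaminants(sig, ann, verbose = verbose)
  list(signal = masked,
       signal_unmasked = sig,
       qc = list(input_pairs = nrow(pairs),
                 kept = dd$kept, duplicates_removed = dd$removed,
                 small_rna_fraction = rep$small_rna_fraction,
                 rrna_fraction = rep$rrna_fraction,
                 masked_signal = total_signal(sig) - total_signal(masked)))
}
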