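#' Single-nucleotide 3'-end signal
#'
#' The central analyte: a sparse, stranded map of polymerase 3'-end
#' positions to counts. Stored as a `data.table` with columns `chrom`,
#' `strand`, `pos` (0-based) and `count`, sorted by (chrom, strand, pos);
#' zero counts are never stored.
#'
#' @param chrom,strand,pos,count Parallel vectors. Rows with identical
#'   (chrom, strand, pos) are summed.
#' @return Object of class `snt_signal`.
#' @export
snt_signal <- function(chrom = character(), strand = character(),
                       pos = integer(), count = integer()) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               strand = as.character(strand),
                               pos = as.integer(pos),
                               count = as.numeric(count))
  if (nrow(dt)) {
    if (any(!dt$strand %in% c("+", "-")))
      stop("signal strand must be '+' or '-'")
    dt <- dt[, list(count = sum(count)), by = c("chrom", "strand", "pos")]
    dt <- dt[count > 0]
    data.table::setorder(dt, chrom, strand, pos)
  }
  class(dt) <- c("snt_signal", class(dt))
  dt
}

#' @export
print.snt_signal <- function(x, ...) {
  cat(sprintf("<snt_signal> %d positions, total signal %.0f\n",
              nrow(x), sum(x$count)))
  invisible(x)
}

#' Total signal (sum of counts)
#' @param signal An [snt_signal()] object.
#' @return Numeric scalar.
#' @export
total_signal <- function(signal) sum(signal$count)

#' Scale a signal by a size factor
#'
#' Divides every count by `factor`, so the total scales exactly by
#' `1/factor`. Composes multiplicatively.
#'
#' @param signal An [snt_signal()] object.
#' @param factor Positive scalar (e.g. a median-of-ratios size factor).
#' @return A scaled `snt_signal` (counts may be non-integer).
#' @export
normalize_signal <- function(signal, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("size factor must be a single positive number")
  out <- data.table::copy(signal)
  out[, count := count / factor]
  out
}

#' Restrict a signal to strand-aware TSS windows
#'
#' Keeps only positions inside the first `window` nt downstream of a TSS
#' (strand-mirrored), with overlapping same-strand windows merged into one
#' region attributed to all member genes.
#'
#' @param signal An [snt_signal()] object.
#' @param genes A [gene_models()] object.
#' @param window Window size in bp (default 200).
#' @return List with `signal` (restricted `snt_signal`) and `regions`
#'   (the merged windows from [tss_windows()]).
#' @export
restrict_to_tss_windows <- function(signal, genes, window = 200L) {
  regions <- tss_windows(genes, size = window, merge = TRUE)
  if (nrow(signal) == 0L || nrow(regions) == 0L) {
    return(list(signal = snt_signal(), regions = regions))
  }
  keep <- overlaps_positions(signal, regions, stranded = TRUE)
  out <- signal[keep]
  class(out) <- class(signal)
  list(signal = out, regions = regions)
}

# logical vector: does each signal position fall in any interval
# (strand-matched when stranded=TRUE; '.' intervals match both strands)
overlaps_positions <- function(signal, intervals, stranded = TRUE) {
  if (nrow(signal) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, nrow(signal)))
  sg <- GenomicRanges::GRanges(signal$chrom,
                               IRanges::IRanges(signal$pos + 1L, width = 1L),
                               strand = signal$strand)
  ig <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1L,
                                                intervals$end),
                               strand = ifelse(intervals$strand == ".", "*",
                                               intervals$strand))
  hits <- GenomicRanges::findOverlaps(sg, ig, ignore.strand = !stranded)
  out <- rep(FALSE, nrow(signal))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Sum signal over regions
#'
#' Strand-matched interval sums of single-nucleotide counts: the analogue
#' of counting reads over a feature reference. Positions at `end` are
#' excluded (half-open convention); intervals with strand `.` match both
#' strands.
#'
#' @param signal An [snt_signal()] object.
#' @param regions Interval data frame.
#' @return Numeric vector of per-region sums, in the order of `regions`.
#' @export
quantify <- function(signal, regions) {
  if (nrow(regions) == 0L) return(numeric(0))
  if (nrow(signal) == 0L) return(rep(0, nrow(regions)))
  sg <- GenomicRanges::GRanges(signal$chrom,
                               IRanges::IRanges(signal$pos + 1L, width = 1L),
                               strand = signal$strand)
  ig <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end),
                               strand = ifelse(regions$strand == ".", "*",
                                               regions$strand))
  hits <- GenomicRanges::findOverlaps(ig, sg)
  out <- rep(0, nrow(regions))
  if (length(hits)) {
    agg <- tapply(signal$count[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}
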