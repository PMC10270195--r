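#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the convention used internally
#' throughout the package. External 1-based formats (GTF) are converted at
#' the parsing boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; must satisfy `start < end`.
#' @param strand Character vector in `+`, `-`, `.` (`.` = unstranded).
#' @param name Optional feature names.
#' @param score Optional numeric scores.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = ".",
                              name = ".", score = 0) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must be non-missing integers")
  bad <- which(df$start < 0L | df$start >= df$end)
  if (length(bad))
    stop(sprintf("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
                 bad[1], df$start[bad[1]], df$end[bad[1]]))
  badstr <- which(!df$strand %in% c("+", "-", "."))
  if (length(badstr))
    stop(sprintf("invalid strand '%s' at row %d", df$strand[badstr[1]], badstr[1]))
  invisible(df)
}

#' Convert intervals to a GRanges object
#'
#' Internal 0-based half-open intervals become 1-based closed `GRanges`;
#' strand `.` maps to `*`.
#'
#' @param x Interval data frame as from [genomic_intervals()].
#' @return A [GenomicRanges::GRanges] object.
#' @export
as_granges <- function(x) {
  strand <- ifelse(x$strand == ".", "*", x$strand)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Gene models and annotation sets
#'
#' A gene model set couples a per-gene table (with strand-aware TSS/TES)
#' to an exon table. `tss` and `tes` are 0-based positions of the first and
#' last transcribed base: for `+` genes `tss = start`, `tes = end - 1`; for
#' `-` genes `tss = end - 1`, `tes = start`.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-` only), `start`, `end`.
#' @param exons data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; exons of a gene must be non-overlapping.
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (gaining `tss`/`tes` columns) and `exons`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (nrow(genes) && !all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  genes$tss <- as.integer(genes$tss)
  genes$tes <- as.integer(genes$tes)
  # exon sanity: within gene span, non-overlapping
  if (nrow(exons)) {
    ex <- exons[order(exons$gene_id, exons$start), ]
    sp <- split(ex, ex$gene_id)
    for (g in sp) {
      if (nrow(g) > 1L && any(g$start[-1] < g$end[-nrow(g)]))
        stop(sprintf("overlapping exons in gene %s", g$gene_id[1]))
    }
    exons <- ex
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Assemble an annotation set
#'
#' Bundles gene models with the contaminant interval classes that the
#' preprocessing step masks (small RNAs, exon 3' ends) or reports on
#' (rRNA), plus a chromosome-size table.
#'
#' @param genes A [gene_models()] object.
#' @param small_rna,rrna Interval data frames (may be empty).
#' @param exon_three_prime_ends Interval data frame; if `NULL`, derived
#'   from the gene models via [exon_three_prime_end_intervals()].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(genes, small_rna = genomic_intervals(),
                           exon_three_prime_ends = NULL,
                           rrna = genomic_intervals(),
                           chrom_sizes = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  if (is.null(exon_three_prime_ends))
    exon_three_prime_ends <- exon_three_prime_end_intervals(genes)
  ann <- structure(list(
    genes = genes,
    small_rna = small_rna,
    exon_three_prime_ends = exon_three_prime_ends,
    rrna = rrna,
    chrom_sizes = chrom_sizes
  ), class = "annotation_set")
  if (!is.null(chrom_sizes)) {
    used <- unique(c(genes$genes$chrom, small_rna$chrom, rrna$chrom))
    missing <- setdiff(used, names(chrom_sizes))
    if (length(missing))
      stop(sprintf("chromosome(s) not in size table: %s",
                   paste(missing, collapse = ", ")))
  }
  ann
}

#' Derive exon 3'-end intervals from gene models
#'
#' The 3'-most `width` bases of every annotated exon, in the direction of
#' transcription. These positions accumulate mature-RNA ends and are
#' masked from the nascent 3'-end signal.
#'
#' @param genes A [gene_models()] object.
#' @param width Number of terminal bases per exon (default 3).
#' @return Interval data frame.
#' @export
exon_three_prime_end_intervals <- function(genes, width = 3L) {
  ex <- genes$exons
  if (nrow(ex) == 0L) return(genomic_intervals())
  w <- pmin(as.integer(width), ex$end - ex$start)
  start <- ifelse(ex$strand == "+", ex$end - w, ex$start)
  end <- ifelse(ex$strand == "+", ex$end, ex$start + w)
  genomic_intervals(ex$chrom, start, end, strand = ex$strand,
                    name = paste0(ex$gene_id, "_exon3p"))
}

#' Strand-aware TSS windows, optionally merged
#'
#' For a `+` gene the window is `[tss, tss + size)`; for a `-` gene it is
#' mirrored to `[tss - size + 1, tss + 1)`. Overlapping same-strand windows
#' are merged into a single region attributed to all member genes.
#'
#' @param genes A [gene_models()] object.
#' @param size Window size in bp downstream of the TSS (default 200).
#' @param merge Merge overlapping same-strand windows (default TRUE).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_ids` (comma-separated member genes).
#' @export
tss_windows <- function(genes, size = 200L, merge = TRUE) {
  g <- genes$genes
  size <- as.integer(size)
  start <- ifelse(g$strand == "+", g$tss, g$tss - size + 1L)
  end <- start + size
  start <- pmax(start, 0L)
  win <- data.frame(chrom = g$chrom, start = as.integer(start),
                    end = as.integer(end), strand = g$strand,
                    gene_ids = g$gene_id, stringsAsFactors = FALSE)
  if (!merge || nrow(win) <= 1L) return(win)
  dt <- data.table::as.data.table(win)
  data.table::setorder(dt, chrom, strand, start)
  grp <- integer(nrow(dt))
  gi <- 0L
  last_end <- -1L
  last_key <- ""
  for (i in seq_len(nrow(dt))) {
    key <- paste0(dt$chrom[i], dt$strand[i])
    if (key != last_key || dt$start[i] >= last_end) {
      gi <- gi + 1L
      last_end <- dt$end[i]
    } else {
      last_end <- max(last_end, dt$end[i])
    }
    last_key <- key
    grp[i] <- gi
  }
  dt[, grp := grp]
  merged <- dt[, list(chrom = chrom[1], start = min(start), end = max(end),
                      strand = strand[1],
                      gene_ids = paste(gene_ids, collapse = ",")),
               by = "grp"]
  merged[, grp := NULL]
  as.data.frame(merged)
}
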