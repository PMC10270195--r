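#' Read a BED file
#'
#' BED uses 0-based half-open coordinates, which is also the internal
#' convention, so no conversion happens. Lines starting with `#`,
#' `track` or `browser` are skipped.
#'
#' @param path Path to a BED file.
#' @param expected_columns Minimum number of tab-separated fields each
#'   line must carry (default 3).
#' @return Interval data frame ([genomic_intervals()] layout); strand is
#'   `.` when column 6 is absent.
#' @export
read_bed <- function(path, expected_columns = 3L) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(genomic_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < expected_columns)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: %d field(s), expected >= %d",
                 lineno[bad[1]], nf[bad[1]], expected_columns))
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, character(1))
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 lineno[bad[1]]))
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop(sprintf("BED validation error at line %d: start=%d end=%d",
                 lineno[bad[1]], start[bad[1]], end[bad[1]]))
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  genomic_intervals(chrom = get(1, NA), start = start, end = end,
                    name = get(4, "."), score = score,
                    strand = get(6, "."))
}

#' Write intervals as BED6
#'
#' @param intervals Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                   df$name, format(df$score, trim = TRUE), df$strand)
  writeLines(if (nrow(df)) lines else character(0), path)
  invisible(path)
}

#' Read a bedGraph file into a single-nucleotide signal
#'
#' bedGraph carries no strand; supply it via `strand` (stranded signal is
#' conventionally stored as one file per strand). Runs are expanded to
#' per-base counts.
#'
#' @param path Path to a bedGraph file.
#' @param strand Strand to assign (`+` or `-`).
#' @return An [snt_signal()] object.
#' @export
read_bedgraph <- function(path, strand = "+") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(snt_signal())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop(sprintf("bedGraph parse error at line %d: %d field(s), expected 4",
                 lineno[bad[1]], nf[bad[1]]))
  m <- matrix(unlist(lapply(fields, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  start <- as.integer(m[, 2])
  end <- as.integer(m[, 3])
  value <- as.numeric(m[, 4])
  widths <- end - start
  if (any(widths <= 0L))
    stop(sprintf("bedGraph validation error at line %d: start >= end",
                 lineno[which(widths <= 0L)[1]]))
  snt_signal(chrom = rep(m[, 1], widths),
             strand = strand,
             pos = unlist(lapply(seq_along(start), function(i)
               seq.int(start[i], end[i] - 1L))),
             count = rep(value, widths))
}

#' Write one strand of a signal as bedGraph
#'
#' Maximal runs of equal nonzero value are emitted as single lines
#' (0-based half-open), sorted by chromosome then start; round-trips
#' losslessly with [read_bedgraph()].
#'
#' @param signal An [snt_signal()] object.
#' @param strand Which strand to write (`+` or `-`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(signal, strand, path) {
  dt <- signal[signal$strand == strand]
  if (nrow(dt) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  dt <- dt[order(dt$chrom, dt$pos)]
  # run boundaries: new chrom, gap in position, or value change
  newrun <- c(TRUE, dt$chrom[-1] != dt$chrom[-nrow(dt)] |
                dt$pos[-1] != dt$pos[-nrow(dt)] + 1L |
                dt$count[-1] != dt$count[-nrow(dt)])
  run <- cumsum(newrun)
  starts <- dt$pos[newrun]
  ends <- dt$pos[c(newrun[-1], TRUE)] + 1L
  chroms <- dt$chrom[newrun]
  values <- dt$count[newrun]
  writeLines(sprintf("%s\t%d\t%d\t%s", chroms, starts, ends,
                     format(values, trim = TRUE, scientific = FALSE)), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, keyed by the
#'   header token before the first whitespace.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  keys <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(keys))
    stop(sprintf("duplicate FASTA header: %s", keys[duplicated(keys)][1]))
  seqs <- toupper(as.character(set))
  names(seqs) <- keys
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a two-column chrom.sizes table
#' @param path Path to a tab-separated chrom/length file.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "size"))
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Write a chrom.sizes table
#' @param sizes Named integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}
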