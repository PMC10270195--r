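# CIGAR helpers: reference-consumed width and terminal soft-clip lengths.
cigar_ops <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(m) || paste(m, collapse = "") != cigar)
    stop(sprintf("malformed CIGAR '%s'", cigar))
  list(len = as.integer(sub("[A-Z=]$", "", m)),
       op = sub("^\\d+", "", m))
}

cigar_ref_width <- function(cigar) {
  ops <- cigar_ops(cigar)
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

cigar_clips <- function(cigar) {
  ops <- cigar_ops(cigar)
  lead <- if (ops$op[1] == "S") ops$len[1] else 0L
  n <- length(ops$op)
  trail <- if (n > 1L && ops$op[n] == "S") ops$len[n] else 0L
  c(lead, trail)
}

#' Read properly paired alignments from a SAM text file
#'
#' Consumes aligner output: one `aligned_pairs` row per proper pair. The
#' UMI is taken from the read-name suffix after the last underscore (the
#' umi_tools extract convention); soft-clip lengths come from the CIGAR
#' and are reported in sequencing order (leading = 5' end of the read as
#' sequenced, i.e. the trailing SAM clip for reverse-strand alignments).
#' Records that are unpaired, not flagged properly paired, or unmapped
#' are dropped with a warning, as are orphan mates at EOF.
#'
#' @param path Path to a SAM file (text, with header).
#' @return An `aligned_pairs` data.table: `name`, `umi`, `chrom`,
#'   `r1_start`, `r1_end`, `r1_strand`, `r2_start`, `r2_end`,
#'   `r2_strand`, `r2_leading_softclip`, `r2_trailing_softclip`,
#'   `clips_stripped`. Coordinates are 0-based half-open aligned spans
#'   (soft-clipped bases consume no reference).
#' @export
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_pairs())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop(sprintf("SAM parse error at alignment line %d: %d field(s), expected >= 11",
                 which(nf < 11L)[1], nf[which(nf < 11L)[1]]))
  qname <- vapply(fields, `[`, character(1), 1L)
  flag <- as.integer(vapply(fields, `[`, character(1), 2L))
  rname <- vapply(fields, `[`, character(1), 3L)
  pos <- as.integer(vapply(fields, `[`, character(1), 4L))
  cigar <- vapply(fields, `[`, character(1), 6L)

  paired <- bitwAnd(flag, 1L) > 0L
  proper <- bitwAnd(flag, 2L) > 0L
  unmapped <- bitwAnd(flag, 4L) > 0L
  drop <- !paired | !proper | unmapped
  if (any(drop))
    warning(sprintf("dropping %d record(s) that are unpaired/improper/unmapped",
                    sum(drop)))
  keep <- which(!drop)
  if (!length(keep)) return(empty_pairs())

  no_umi <- !grepl("_", qname[keep])
  if (any(no_umi))
    stop(sprintf("read '%s' has no UMI suffix in its name",
                 qname[keep][no_umi][1]))

  rec <- data.table::data.table(
    qname = qname[keep], flag = flag[keep], rname = rname[keep],
    start = pos[keep] - 1L, cigar = cigar[keep])
  rec[, end := start + vapply(cigar, cigar_ref_width, integer(1))]
  rec[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  rec[, mate := ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L)]

  cl <- t(vapply(rec$cigar, cigar_clips, integer(2)))
  rec[, sam_lead := cl[, 1]]
  rec[, sam_trail := cl[, 2]]

  r1 <- rec[mate == 1L]
  r2 <- rec[mate == 2L]
  common <- intersect(r1$qname, r2$qname)
  n_orphan <- (nrow(r1) - length(common)) + (nrow(r2) - length(common))
  if (n_orphan > 0L)
    warning(sprintf("dropping %d orphan mate(s) without a partner", n_orphan))
  if (!length(common)) return(empty_pairs())
  data.table::setkey(r1, qname)
  data.table::setkey(r2, qname)
  r1 <- r1[common]
  r2 <- r2[common]
  if (any(r1$rname != r2$rname)) {
    bad <- which(r1$rname != r2$rname)
    warning(sprintf("dropping %d pair(s) with mates on different chromosomes",
                    length(bad)))
    r1 <- r1[-bad]; r2 <- r2[-bad]
  }
  # sequencing-order clips: leading = 5' of the read as sequenced
  lead <- ifelse(r2$strand == "-", r2$sam_trail, r2$sam_lead)
  trail <- ifelse(r2$strand == "-", r2$sam_lead, r2$sam_trail)
  out <- data.table::data.table(
    name = r1$qname,
    umi = sub(".*_", "", r1$qname),
    chrom = r1$rname,
    r1_start = r1$start, r1_end = r1$end, r1_strand = r1$strand,
    r2_start = r2$start, r2_end = r2$end, r2_strand = r2$strand,
    r2_leading_softclip = as.integer(lead),
    r2_trailing_softclip = as.integer(trail),
    clips_stripped = FALSE)
  class(out) <- c("aligned_pairs", class(out))
  out
}

empty_pairs <- function() {
  out <- data.table::data.table(
    name = character(), umi = character(), chrom = character(),
    r1_start = integer(), r1_end = integer(), r1_strand = character(),
    r2_start = integer(), r2_end = integer(), r2_strand = character(),
    r2_leading_softclip = integer(), r2_trailing_softclip = integer(),
    clips_stripped = logical())
  class(out) <- c("aligned_pairs", class(out))
  out
}

#' Write aligned pairs as SAM text
#'
#' Emits a minimal valid SAM file (header with `@SQ` lines, two alignment
#' records per pair, SEQ/QUAL omitted as `*`). Soft clips recorded in
#' sequencing order are placed on the correct CIGAR end for the mapping
#' orientation. Inverse of [read_sam_pairs()] on its own output.
#'
#' @param pairs An `aligned_pairs` table.
#' @param chrom_sizes Named integer vector for the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, chrom_sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  if (nrow(pairs) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  flag1 <- 1L + 2L + 64L +
    ifelse(pairs$r1_strand == "-", 16L, 0L) +
    ifelse(pairs$r2_strand == "-", 32L, 0L)
  flag2 <- 1L + 2L + 128L +
    ifelse(pairs$r2_strand == "-", 16L, 0L) +
    ifelse(pairs$r1_strand == "-", 32L, 0L)
  cig1 <- sprintf("%dM", pairs$r1_end - pairs$r1_start)
  m2 <- sprintf("%dM", pairs$r2_end - pairs$r2_start)
  # sequencing-order leading clip sits at the SAM-left end only for '+'
  sam_lead <- ifelse(pairs$r2_strand == "-", pairs$r2_trailing_softclip,
                     pairs$r2_leading_softclip)
  sam_trail <- ifelse(pairs$r2_strand == "-", pairs$r2_leading_softclip,
                      pairs$r2_trailing_softclip)
  cig2 <- paste0(ifelse(sam_lead > 0L, sprintf("%dS", sam_lead), ""),
                 m2,
                 ifelse(sam_trail > 0L, sprintf("%dS", sam_trail), ""))
  l1 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t*\t*",
                pairs$name, flag1, pairs$chrom, pairs$r1_start + 1L, cig1,
                pairs$r2_start + 1L)
  l2 <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t*\t*",
                pairs$name, flag2, pairs$chrom, pairs$r2_start + 1L, cig2,
                pairs$r1_start + 1L)
  out <- character(2L * nrow(pairs))
  out[seq(1L, by = 2L, length.out = nrow(pairs))] <- l1
  out[seq(2L, by = 2L, length.out = nrow(pairs))] <- l2
  writeLines(c(hdr, out), path)
  invisible(path)
}
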