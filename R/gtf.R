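#' Read gene models from a GTF file
#'
#' Parses `exon` features, groups them by the `gene_id` attribute, and
#' derives the strand-aware TSS/TES. GTF's 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention (an exon at
#' GTF 101..200 becomes `[100, 200)`).
#'
#' @param path Path to a GTF file.
#' @return A [gene_models()] object.
#' @export
read_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  gene_line_ids <- character(0)
  ex <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L)
      stop(sprintf("GTF parse error at line %d: %d field(s), expected 9",
                   i, length(f)))
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", f[9])
    if (identical(gid, f[9]))
      stop(sprintf("GTF parse error at line %d: no gene_id attribute", i))
    if (f[3] == "gene") {
      gene_line_ids <- c(gene_line_ids, gid)
    } else if (f[3] == "exon") {
      ex[[length(ex) + 1L]] <- data.frame(
        gene_id = gid, chrom = f[1],
        start = as.integer(f[4]) - 1L,  # 1-based inclusive -> 0-based half-open
        end = as.integer(f[5]),
        strand = f[7], stringsAsFactors = FALSE)
    }
  }
  exons <- if (length(ex)) do.call(rbind, ex) else
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  empties <- setdiff(gene_line_ids, exons$gene_id)
  if (length(empties))
    warning(sprintf("skipping %d gene(s) with zero exons: %s",
                    length(empties), paste(empties, collapse = ", ")))
  if (nrow(exons) == 0L) {
    return(gene_models(
      genes = data.frame(gene_id = character(), chrom = character(),
                         strand = character(), start = integer(),
                         end = integer()),
      exons = exons))
  }
  dt <- data.table::as.data.table(exons)
  g <- dt[, list(chrom = chrom[1], strand = strand[1],
                 start = min(start), end = max(end)), by = "gene_id"]
  gene_models(genes = as.data.frame(g), exons = exons)
}

#' Write gene models as GTF
#'
#' Emits one `gene` line and one `exon` line per exon, converting back to
#' GTF's 1-based inclusive coordinates; exact inverse of
#' [read_gtf_genes()] on its output.
#'
#' @param genes A [gene_models()] object.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path, source = "buttseq") {
  g <- genes$genes
  ex <- genes$exons
  glines <- sprintf('%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                    g$chrom, source, g$start + 1L, g$end, g$strand, g$gene_id)
  elines <- sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                    ex$chrom, source, ex$start + 1L, ex$end, ex$strand,
                    ex$gene_id)
  # interleave per gene for readability: gene line then its exons
  out <- character(0)
  exg <- split(elines, ex$gene_id)
  for (i in seq_len(nrow(g))) {
    out <- c(out, glines[i], exg[[g$gene_id[i]]])
  }
  writeLines(out, path)
  invisible(path)
}
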