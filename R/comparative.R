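#' Merge pause peaks across two conditions
#'
#' Per gene: if both conditions called a site, the anchor is the site
#' with the larger pooled count (ties go to the TSS-proximal one); if
#' only one condition has a site, that site is used. Every anchor carries
#' a provenance tag (`both`, `A_only`, `B_only`).
#'
#' @param sites_a,sites_b Per-gene pause tables (one row per gene, as
#'   from [top_pause_per_gene()]), computed with identical parameters.
#' @return data.frame of unified anchors with a `provenance` column.
#' @export
merge_pause_peaks <- function(sites_a, sites_b) {
  all_genes <- union(sites_a$gene_id, sites_b$gene_id)
  rows <- lapply(all_genes, function(g) {
    a <- sites_a[sites_a$gene_id == g, , drop = FALSE]
    b <- sites_b[sites_b$gene_id == g, , drop = FALSE]
    if (nrow(a) && nrow(b)) {
      pick <- if (a$count[1] > b$count[1]) a[1, ]
        else if (b$count[1] > a$count[1]) b[1, ]
        else if (a$offset_from_tss[1] <= b$offset_from_tss[1]) a[1, ]
        else b[1, ]
      pick$provenance <- "both"
      pick
    } else if (nrow(a)) {
      a <- a[1, ]; a$provenance <- "A_only"; a
    } else {
      b <- b[1, ]; b$provenance <- "B_only"; b
    }
  })
  do.call(rbind, rows)
}

#' Classify pause/body concordance between two conditions
#'
#' For each anchored gene, the pause region (TSS to the pause) and the
#' elongation region (`body_length` bp downstream of the pause) are
#' quantified in both conditions, normalized by per-condition size
#' factors, and classified by a symmetric fold-change rule:
#' `A_higher` when normA/normB >= `fc_threshold`, `B_higher` when
#' <= 1/`fc_threshold`, otherwise `same`. Genes where both conditions
#' fall below `min_count` in a region are excluded. Size factors are
#' computed over merged TSS-window counts unless supplied.
#'
#' @param signal_a,signal_b [snt_signal()] objects for the two
#'   conditions.
#' @param anchors Merged per-gene pause anchors
#'   ([merge_pause_peaks()]).
#' @param genes A [gene_models()] object.
#' @param factors Optional length-2 size factors (A, B).
#' @param body_length Elongation window in bp (default 1000).
#' @param fc_threshold Fold-change threshold (default 2).
#' @param min_count Minimum raw count filter (default 10).
#' @return List: `records` (per-gene classes), `grid` (3x3 counts,
#'   pause class x body class), `fractions` (concordant,
#'   single_discordant, double_discordant).
#' @export
concordance_classify <- function(signal_a, signal_b, anchors, genes,
                                 factors = NULL, body_length = 1000L,
                                 fc_threshold = 2, min_count = 10) {
  g <- genes$genes
  if (is.null(factors)) {
    win <- tss_windows(genes, size = 200L, merge = TRUE)
    cnt <- cbind(A = quantify(signal_a, win), B = quantify(signal_b, win))
    factors <- size_factors(cnt)
  }
  classify <- function(a, b) {
    if (a / b >= fc_threshold) "A_higher"
    else if (a / b <= 1 / fc_threshold) "B_higher"
    else "same"
  }
  levels3 <- c("A_higher", "same", "B_higher")
  rows <- list()
  for (i in seq_len(nrow(anchors))) {
    an <- anchors[i, ]
    gene <- g[g$gene_id == an$gene_id, , drop = FALSE]
    if (nrow(gene) == 0L || an$offset_from_tss < 1L) next
    gene <- gene[1, ]
    plus <- gene$strand == "+"
    p <- an$position
    pr <- if (plus) c(gene$tss, p + 1L) else c(p, gene$tss + 1L)
    br <- if (plus) c(p + 1L, min(p + 1L + body_length, gene$tes + 1L))
          else c(max(p - body_length, gene$tes), p)
    if (br[2] <= br[1]) next
    region <- function(lim) data.frame(chrom = gene$chrom, start = lim[1],
                                       end = lim[2], name = ".", score = 0,
                                       strand = gene$strand)
    pa <- quantify(signal_a, region(pr)); pb <- quantify(signal_b, region(pr))
    ba <- quantify(signal_a, region(br)); bb <- quantify(signal_b, region(br))
    if ((pa < min_count && pb < min_count) ||
        (ba < min_count && bb < min_count)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene$gene_id,
      pause_class = classify(pa / factors[1], pb / factors[2]),
      body_class = classify(ba / factors[1], bb / factors[2]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no classifiable genes (all excluded)")
  rec <- do.call(rbind, rows)
  rec$pause_class <- factor(rec$pause_class, levels = levels3)
  rec$body_class <- factor(rec$body_class, levels = levels3)
  grid <- table(pause = rec$pause_class, body = rec$body_class)
  n <- nrow(rec)
  concordant <- (grid["A_higher", "A_higher"] + grid["same", "same"] +
                   grid["B_higher", "B_higher"]) / n
  double_disc <- (grid["A_higher", "B_higher"] +
                    grid["B_higher", "A_higher"]) / n
  fractions <- c(concordant = as.numeric(concordant),
                 single_discordant = 1 - as.numeric(concordant) -
                   as.numeric(double_disc),
                 double_discordant = as.numeric(double_disc))
  list(records = rec, grid = grid, fractions = fractions,
       size_factors = factors)
}

#' Exon-only time-course quantification
#'
#' Strand-matched exon-interval sums per gene per timepoint (intronic
#' signal contributes nothing), size-factor-normalized across timepoints
#' by median-of-ratios.
#'
#' @param signals Named list of [snt_signal()] objects, one per
#'   timepoint (names e.g. `ZT2` ... `ZT22`).
#' @param genes A [gene_models()] object.
#' @param normalize Apply median-of-ratios across timepoints (default
#'   TRUE).
#' @return A genes x timepoints matrix; attribute `size_factors` when
#'   normalized.
#' @export
circadian_quantify <- function(signals, genes, normalize = TRUE) {
  stopifnot(length(signals) >= 2L)
  ex <- genes$exons
  regions <- data.frame(chrom = ex$chrom, start = ex$start, end = ex$end,
                        name = ex$gene_id, score = 0, strand = ex$strand,
                        stringsAsFactors = FALSE)
  gene_ids <- genes$genes$gene_id
  cols <- lapply(signals, function(sig) {
    percount <- quantify(sig, regions)
    as.numeric(rowsum(percount, ex$gene_id)[gene_ids, 1])
  })
  mat <- matrix(unlist(cols), nrow = length(gene_ids),
                dimnames = list(gene_ids, names(signals)))
  if (normalize) {
    f <- tryCatch(size_factors(mat), error = function(e) NULL)
    if (!is.null(f)) {
      mat <- sweep(mat, 2, f, "/")
      attr(mat, "size_factors") <- f
    }
  }
  mat
}

#' Normalize each gene's time course to its peak timepoint
#'
#' Row-wise division by the row maximum; all-zero rows are dropped with
#' a message. Idempotent.
#'
#' @param mat Genes x timepoints matrix.
#' @return Matrix with row maxima exactly 1.
#' @export
normalize_to_peak <- function(mat) {
  mx <- apply(mat, 1, max)
  zero <- mx <= 0
  if (any(zero)) {
    message(sprintf("normalize_to_peak: dropping %d all-zero gene(s)",
                    sum(zero)))
    mat <- mat[!zero, , drop = FALSE]
    mx <- mx[!zero]
  }
  sweep(mat, 1, mx, "/")
}

#' Per-gene peak and trough timepoints
#'
#' @param mat Genes x timepoints matrix (raw or normalized), with
#'   timepoint column names.
#' @return data.frame: `gene_id`, `peak`, `trough`, `amplitude`
#'   (peak/trough; `Inf` flagged via `infinite_amplitude` when the
#'   trough is 0).
#' @export
peak_trough <- function(mat) {
  tp <- colnames(mat)
  pk <- apply(mat, 1, which.max)
  tr <- apply(mat, 1, which.min)
  pv <- mat[cbind(seq_len(nrow(mat)), pk)]
  tv <- mat[cbind(seq_len(nrow(mat)), tr)]
  amp <- ifelse(tv > 0, pv / tv, Inf)
  data.frame(gene_id = rownames(mat), peak = tp[pk], trough = tp[tr],
             amplitude = amp, infinite_amplitude = !is.finite(amp),
             stringsAsFactors = FALSE)
}
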