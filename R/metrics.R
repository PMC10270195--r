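#' Pause-anchored pausing index
#'
#' Pause region: TSS to the highest pause (inclusive); body region: the
#' `body_length` bp immediately downstream of the pause, truncated at the
#' TES with a warning if the gene ends first. The index is the ratio of
#' signal densities (signal/length); set `raw_ratio = TRUE` for the plain
#' signal ratio. Genes with zero body signal are flagged (`ok = FALSE`)
#' so they can be excluded from ECDFs.
#'
#' @param gene One row of `gene_models$genes`.
#' @param pause One pause-site row for that gene.
#' @param signal An [snt_signal()] object.
#' @param body_length Body window in bp (default 1000; 2000 is the
#'   common alternative).
#' @param raw_ratio Use raw signal ratio instead of densities.
#' @return One-row data.frame: gene_id, pause/body signal, lengths,
#'   `index`, `ok`.
#' @export
pausing_index_anchored <- function(gene, pause, signal, body_length = 1000L,
                                   raw_ratio = FALSE) {
  stopifnot(pause$gene_id == gene$gene_id, pause$offset_from_tss >= 1L)
  plus <- gene$strand == "+"
  p <- pause$position
  if (plus) {
    pr <- c(gene$tss, p + 1L)               # [tss, pause]
    br <- c(p + 1L, p + 1L + body_length)   # (pause, pause + L]
    if (br[2] > gene$tes + 1L) {
      warning(sprintf("%s: body region truncated at TES", gene$gene_id))
      br[2] <- gene$tes + 1L
    }
  } else {
    pr <- c(p, gene$tss + 1L)
    br <- c(p - body_length, p)
    if (br[1] < gene$tes) {
      warning(sprintf("%s: body region truncated at TES", gene$gene_id))
      br[1] <- gene$tes
    }
  }
  region <- function(lim) data.frame(chrom = gene$chrom, start = lim[1],
                                     end = lim[2], name = ".", score = 0,
                                     strand = gene$strand)
  ps <- quantify(signal, region(pr))
  bs <- quantify(signal, region(br))
  plen <- pr[2] - pr[1]
  blen <- br[2] - br[1]
  idx <- if (bs > 0) {
    if (raw_ratio) ps / bs else (ps / plen) / (bs / blen)
  } else NA_real_
  data.frame(gene_id = gene$gene_id, pause_signal = ps, body_signal = bs,
             pause_length = plen, body_length = blen, index = idx,
             ok = bs > 0, stringsAsFactors = FALSE)
}

#' Fixed-window pausing index
#'
#' Promoter region `[tss - upstream, tss + downstream)` (strand-mirrored)
#' against the remaining gene body `[tss + downstream, tes]`; density
#' ratio as in [pausing_index_anchored()].
#'
#' @param gene One row of `gene_models$genes`.
#' @param signal An [snt_signal()] object.
#' @param upstream,downstream Promoter window bounds (default -50/+200).
#' @param raw_ratio Use raw signal ratio.
#' @return One-row data.frame as for [pausing_index_anchored()].
#' @export
pausing_index_fixed <- function(gene, signal, upstream = 50L,
                                downstream = 200L, raw_ratio = FALSE) {
  glen <- abs(gene$tes - gene$tss) + 1L
  if (glen <= upstream + downstream)
    stop(sprintf("%s: gene too short for fixed-window index", gene$gene_id))
  plus <- gene$strand == "+"
  if (plus) {
    pr <- c(gene$tss - upstream, gene$tss + downstream)
    br <- c(gene$tss + downstream, gene$tes + 1L)
  } else {
    pr <- c(gene$tss - downstream + 1L, gene$tss + upstream + 1L)
    br <- c(gene$tes, gene$tss - downstream + 1L)
  }
  pr[1] <- max(pr[1], 0L)
  region <- function(lim) data.frame(chrom = gene$chrom, start = lim[1],
                                     end = lim[2], name = ".", score = 0,
                                     strand = gene$strand)
  ps <- quantify(signal, region(pr))
  bs <- quantify(signal, region(br))
  plen <- pr[2] - pr[1]
  blen <- br[2] - br[1]
  idx <- if (bs > 0) {
    if (raw_ratio) ps / bs else (ps / plen) / (bs / blen)
  } else NA_real_
  data.frame(gene_id = gene$gene_id, pause_signal = ps, body_signal = bs,
             pause_length = plen, body_length = blen, index = idx,
             ok = bs > 0, stringsAsFactors = FALSE)
}

#' Pausing indices for a cohort of genes
#'
#' @param genes A [gene_models()] object.
#' @param pauses Per-gene pause table (see [top_pause_per_gene()]);
#'   ignored in `"fixed"` mode.
#' @param signal An [snt_signal()] object.
#' @param mode `"anchored"` or `"fixed"`.
#' @param body_length Anchored-mode body window (bp).
#' @param raw_ratio Use raw signal ratios.
#' @return data.frame, one row per computable gene.
#' @export
pausing_indices <- function(genes, pauses, signal, mode = c("anchored", "fixed"),
                            body_length = 1000L, raw_ratio = FALSE) {
  mode <- match.arg(mode)
  g <- genes$genes
  rows <- list()
  for (i in seq_len(nrow(g))) {
    gene <- g[i, ]
    res <- tryCatch(suppressWarnings({
      if (mode == "anchored") {
        p <- pauses[pauses$gene_id == gene$gene_id, , drop = FALSE]
        if (nrow(p) == 0L || p$offset_from_tss[1] < 1L) NULL
        else pausing_index_anchored(gene, p[1, ], signal,
                                    body_length = body_length,
                                    raw_ratio = raw_ratio)
      } else {
        pausing_index_fixed(gene, signal, raw_ratio = raw_ratio)
      }
    }), error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), pause_signal = numeric(),
                      body_signal = numeric(), pause_length = integer(),
                      body_length = integer(), index = numeric(),
                      ok = logical()))
  do.call(rbind, rows)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the exact supremum of the ECDF difference over the pooled
#' sample points; the p-value is asymptotic (Kolmogorov distribution with
#' effective n = nx*ny/(nx+ny)).
#'
#' @param x,y Numeric samples (length >= 1).
#' @return List: `D`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Median-of-ratios size factors
#'
#' The reference for each feature is its geometric mean across samples
#' (features with any zero are excluded from the reference set); the size
#' factor of a sample is the median over features of its count divided by
#' the reference.
#'
#' @param counts Numeric features x samples matrix.
#' @return Numeric vector of positive per-sample factors (named by
#'   column if the matrix has column names).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("need at least one sample")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no feature with all-positive counts across samples")
  m <- counts[allpos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  f <- apply(m / ref, 2, stats::median)
  if (any(f <= 0)) stop("non-positive size factor")
  stats::setNames(as.numeric(f), colnames(counts))
}
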