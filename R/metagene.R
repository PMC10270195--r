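#' Build an anchored or scaled metagene matrix
#'
#' Reference-point mode extracts `upstream + downstream` single-bp bins
#' around each TSS (strand-aware, so columns run 5' to 3'); scale-region
#' mode linearly rescales each gene body to `body_bins` columns. Genes
#' shorter than `downstream` in reference-point mode are zero-padded
#' beyond their TES and flagged.
#'
#' @param signal An [snt_signal()] object.
#' @param genes A [gene_models()] object.
#' @param mode `"tss"` (reference point) or `"scale"`.
#' @param upstream,downstream Window in bp around the TSS (`"tss"` mode).
#' @param min_gene_length Keep genes at least this long (default 5000).
#' @param plus_strand_only Keep only `+` genes (a common visualization
#'   restriction); default FALSE.
#' @param body_bins Number of columns in `"scale"` mode.
#' @return A numeric matrix (rows = genes, rownames = gene ids) with
#'   attributes `anchor_col` (column index of the TSS in `"tss"` mode)
#'   and `padded` (logical per row).
#' @export
build_matrix <- function(signal, genes, mode = c("tss", "scale"),
                         upstream = 200L, downstream = 1000L,
                         min_gene_length = 5000L, plus_strand_only = FALSE,
                         body_bins = 100L) {
  mode <- match.arg(mode)
  g <- genes$genes
  glen <- abs(g$tes - g$tss) + 1L
  keep <- glen >= min_gene_length
  if (plus_strand_only) keep <- keep & g$strand == "+"
  g <- g[keep, , drop = FALSE]
  glen <- glen[keep]
  if (nrow(g) == 0L) stop("no genes pass the length/strand filter")
  width <- if (mode == "tss") upstream + downstream else body_bins
  mat <- matrix(0, nrow = nrow(g), ncol = width,
                dimnames = list(g$gene_id, NULL))
  padded <- logical(nrow(g))
  sig_by <- split(seq_len(nrow(signal)),
                  paste(signal$chrom, signal$strand))
  for (i in seq_len(nrow(g))) {
    key <- paste(g$chrom[i], g$strand[i])
    idx <- sig_by[[key]]
    if (is.null(idx)) next
    pos <- signal$pos[idx]
    cnt <- signal$count[idx]
    sgn <- if (g$strand[i] == "+") 1L else -1L
    local <- sgn * (pos - g$tss[i])   # 0 = TSS, increasing downstream
    if (mode == "tss") {
      inwin <- local >= -upstream & local < downstream
      if (any(inwin)) {
        col <- local[inwin] + upstream + 1L
        agg <- tapply(cnt[inwin], col, sum)
        mat[i, as.integer(names(agg))] <- as.numeric(agg)
      }
      padded[i] <- glen[i] < downstream
    } else {
      inwin <- local >= 0L & local < glen[i]
      if (any(inwin)) {
        bin <- pmin(floor(local[inwin] / glen[i] * body_bins) + 1L, body_bins)
        agg <- tapply(cnt[inwin], bin, sum)
        mat[i, as.integer(names(agg))] <- as.numeric(agg)
      }
    }
  }
  attr(mat, "anchor_col") <- if (mode == "tss") upstream + 1L else NA_integer_
  attr(mat, "padded") <- padded
  mat
}

#' Summarize a metagene matrix with bootstrap confidence bands
#'
#' Rows are ranked by total signal; the top and bottom
#' `ceiling(trim_fraction * N)` rows are removed as outliers, a
#' pseudocount is added, values are log2-transformed, and the per-column
#' mean with a percentile bootstrap confidence interval over row
#' resampling is returned.
#'
#' @param mat Matrix from [build_matrix()].
#' @param trim_fraction Fraction trimmed from each tail (default 0.001).
#' @param pseudocount Added before log2 (default 1).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param ci Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return data.frame: `position` (1-based column), `mean`, `lower`,
#'   `upper`; attribute `n_regions` = rows used after trimming.
#' @export
summarize_metagene <- function(mat, trim_fraction = 0.001, pseudocount = 1,
                               n_boot = 10000L, ci = 0.95, seed = 1L) {
  set.seed(seed)
  n <- nrow(mat)
  k <- as.integer(ceiling(trim_fraction * n))
  if (n - 2L * k < 10L) stop("too few rows after trimming (need >= 10)")
  if (k > 0L) {
    ord <- order(rowSums(mat))
    keep <- ord[(k + 1L):(n - k)]
    mat <- mat[keep, , drop = FALSE]
  }
  lm2 <- log2(mat + pseudocount)
  mu <- colMeans(lm2)
  nr <- nrow(lm2)
  alpha <- (1 - ci) / 2
  # chunked indicator-matrix bootstrap of column means over row resampling
  boot_means <- matrix(NA_real_, nrow = n_boot, ncol = ncol(lm2))
  chunk <- 500L
  done <- 0L
  while (done < n_boot) {
    b <- min(chunk, n_boot - done)
    idx <- matrix(sample.int(nr, b * nr, replace = TRUE), nrow = b)
    W <- matrix(0, nrow = b, ncol = nr)
    for (j in seq_len(b)) {
      tb <- tabulate(idx[j, ], nbins = nr)
      W[j, ] <- tb
    }
    boot_means[(done + 1L):(done + b), ] <- (W %*% lm2) / nr
    done <- done + b
  }
  lo <- apply(boot_means, 2, stats::quantile, probs = alpha, names = FALSE)
  hi <- apply(boot_means, 2, stats::quantile, probs = 1 - alpha,
              names = FALSE)
  out <- data.frame(position = seq_len(ncol(lm2)), mean = mu,
                    lower = lo, upper = hi)
  attr(out, "n_regions") <- nr
  out
}
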