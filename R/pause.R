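#' Pause detection parameters
#'
#' Defaults are the standard parameters for single-nucleotide pause
#' calling on nascent 3'-end data: window 100, minimum intensity 5,
#' 10,000 bootstraps, p-value threshold 1e-5, and a 200-nt search region
#' downstream of the TSS.
#'
#' @param window Null window size in bp, centered on the candidate.
#' @param min_intensity Minimum single-position count for a candidate.
#' @param n_bootstraps Number of bootstrap resamples of the null.
#' @param p_threshold Emission threshold on the p-value.
#' @param search_region TSS-downstream search region in bp.
#' @return A validated `pda_params` list.
#' @export
pda_params <- function(window = 100L, min_intensity = 5L,
                       n_bootstraps = 10000L, p_threshold = 1e-5,
                       search_region = 200L) {
  p <- list(window = as.integer(window),
            min_intensity = as.integer(min_intensity),
            n_bootstraps = as.integer(n_bootstraps),
            p_threshold = p_threshold,
            search_region = as.integer(search_region))
  if (any(unlist(p[c(1, 2, 3, 5)]) <= 0L))
    stop("pda parameters must be positive")
  if (p$p_threshold <= 0 || p$p_threshold >= 1)
    stop("p_threshold must be in (0, 1)")
  class(p) <- "pda_params"
  p
}

# Bootstrap null: T reads dropped i.i.d. uniformly over W positions;
# statistic = the maximum single-position count of each resample.
# Returns sorted max counts, cached per (T, W) within one detect run.
null_max_counts <- function(total, width, n_boot, cache = NULL) {
  key <- sprintf("T%d.W%d", total, width)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  m <- stats::rmultinom(n_boot, total, rep(1 / width, width))
  mx <- do.call(pmax, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  if (!is.null(cache)) cache[[key]] <- mx
  mx
}

# Bonferroni (union bound) upper tail for the multinomial maximum:
# P(max >= c) <= W * P(Binom(T, 1/W) >= c)
analytic_max_tail <- function(count, total, width) {
  min(1, width * stats::pbinom(count - 1L, total, 1 / width,
                               lower.tail = FALSE))
}

#' Bootstrap p-value for a candidate pause position
#'
#' Null model: the window's `total` reads fall i.i.d. uniformly over its
#' `width` positions; the p-value is the add-one-corrected fraction of
#' resamples whose maximum single-position count reaches the candidate's
#' count, `p = (1 + k) / (n_boot + 1)`. When no resample reaches the
#' count (`k = 0`) the add-one floor `1/(n_boot+1)` would mask smaller
#' p-values, so the analytic Bonferroni upper bound on the multinomial
#' maximum is reported instead (capped at the floor).
#'
#' @param count Candidate position count.
#' @param total Total reads in the window.
#' @param width Number of positions in the window.
#' @param n_boot Number of resamples.
#' @param null_max Optional precomputed resample maxima (from a shared
#'   cache); otherwise drawn here.
#' @return A p-value in (0, 1].
#' @export
pause_null_pvalue <- function(count, total, width, n_boot = 10000L,
                              null_max = NULL) {
  if (count > total) stop("count cannot exceed window total")
  if (is.null(null_max))
    null_max <- null_max_counts(total, width, n_boot)
  k <- sum(null_max >= count)
  if (k == 0L)
    return(min(analytic_max_tail(count, total, width), 1 / (n_boot + 1)))
  (1 + k) / (length(null_max) + 1)
}

#' Detect single-nucleotide pause sites
#'
#' Restricts the signal to strand-aware TSS windows (`search_region` nt,
#' overlapping same-strand windows merged), then tests every position
#' with count at least `min_intensity` against a bootstrap uniform null
#' within a `window`-sized window centered on the candidate and clipped
#' at the search-region boundary. Sites with p-value at or below
#' `p_threshold` are emitted, one row per (gene, position); positions in
#' a merged region are attributed to every member gene whose own window
#' contains them.
#'
#' @param signal An [snt_signal()] object (genome-wide; restriction is
#'   applied internally).
#' @param genes A [gene_models()] object.
#' @param params A [pda_params()] object.
#' @param seed Integer seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return data.frame of pause sites: `gene_id`, `chrom`, `strand`,
#'   `position`, `count`, `p_value`, `offset_from_tss`.
#' @export
detect_pauses <- function(signal, genes, params = pda_params(), seed = 1L) {
  set.seed(seed)
  res <- restrict_to_tss_windows(signal, genes, window = params$search_region)
  sig <- res$signal
  regions <- res$regions
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), position = integer(),
                      count = numeric(), p_value = numeric(),
                      offset_from_tss = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  g <- genes$genes
  cache <- new.env(parent = emptyenv())
  out <- vector("list", nrow(regions))
  for (ri in seq_len(nrow(regions))) {
    r <- regions[ri, ]
    rs <- sig[sig$chrom == r$chrom & sig$strand == r$strand &
                sig$pos >= r$start & sig$pos < r$end]
    if (nrow(rs) == 0L) next
    cand <- which(rs$count >= params$min_intensity)
    if (!length(cand)) next
    hits <- list()
    for (ci in cand) {
      x <- rs$pos[ci]
      c_x <- rs$count[ci]
      half <- params$window %/% 2L
      w_lo <- max(x - half, r$start)
      w_hi <- min(w_lo + params$window, r$end)   # clip at region boundary
      w_lo <- max(min(w_lo, w_hi - params$window), r$start)
      width <- w_hi - w_lo
      total <- sum(rs$count[rs$pos >= w_lo & rs$pos < w_hi])
      # sound pre-screen: P(max >= c) >= P(single position >= c); when even
      # the single-position binomial tail exceeds the threshold, the
      # bootstrap p cannot pass and the resampling is skipped
      lower <- stats::pbinom(c_x - 1, as.integer(total), 1 / width,
                             lower.tail = FALSE)
      if (lower > params$p_threshold) next
      p <- pause_null_pvalue(
        c_x, as.integer(total), as.integer(width),
        n_boot = params$n_bootstraps,
        null_max = null_max_counts(as.integer(total), as.integer(width),
                                   params$n_bootstraps, cache))
      if (p <= params$p_threshold)
        hits[[length(hits) + 1L]] <- list(pos = x, count = c_x, p = p)
    }
    if (!length(hits)) next
    # attribute each hit to member genes whose own window contains it
    members <- g[g$gene_id %in% strsplit(r$gene_ids, ",")[[1]], ]
    rows <- list()
    for (h in hits) {
      for (mi in seq_len(nrow(members))) {
        m <- members[mi, ]
        offset <- if (m$strand == "+") h$pos - m$tss else m$tss - h$pos
        if (offset >= 0L && offset < params$search_region) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = m$gene_id, chrom = m$chrom, strand = m$strand,
            position = h$pos, count = h$count, p_value = h$p,
            offset_from_tss = as.integer(offset),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) out[[ri]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Keep the highest pause per gene
#'
#' When a gene has multiple called pauses, keeps the one with the largest
#' count; ties go to the most TSS-proximal site (smallest offset).
#'
#' @param sites Pause-site data frame from [detect_pauses()].
#' @return One row per gene.
#' @export
top_pause_per_gene <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  ord <- order(sites$gene_id, -sites$count, sites$offset_from_tss)
  s <- sites[ord, ]
  s[!duplicated(s$gene_id), , drop = FALSE]
}

#' Position frequency matrix around pause sites
#'
#' Extracts strand-corrected sequences `flank` nt either side of each
#' pause base (reverse complement for minus-strand genes) and tabulates
#' per-position base frequencies. Sites within `flank` of a contig edge
#' are skipped with a warning.
#'
#' @param sites Pause-site data frame.
#' @param genome Named character vector of chromosome sequences.
#' @param flank Flank size in nt (default 10; matrix width `2*flank+1`,
#'   center column = the pause base).
#' @return A 4 x (2*flank+1) matrix of A/C/G/T frequencies; every column
#'   sums to 1. Attribute `n_sites` records the sequences used.
#' @export
extract_pause_motif <- function(sites, genome, flank = 10L) {
  stopifnot(flank >= 1L)
  missing <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing))
    stop(sprintf("site on missing chromosome: %s", missing[1]))
  width <- 2L * flank + 1L
  lens <- nchar(genome)[sites$chrom]
  ok <- sites$position - flank >= 0L & sites$position + flank < lens
  if (any(!ok))
    warning(sprintf("skipping %d site(s) within %d nt of a contig edge",
                    sum(!ok), flank))
  s <- sites[ok, , drop = FALSE]
  if (nrow(s) == 0L) stop("no sites with full flanks")
  seqs <- substring(genome[s$chrom], s$position - flank + 1L,
                    s$position + flank + 1L)
  dss <- Biostrings::DNAStringSet(seqs)
  neg <- s$strand == "-"
  if (any(neg)) dss[neg] <- Biostrings::reverseComplement(dss[neg])
  cm <- Biostrings::consensusMatrix(dss, as.prob = TRUE,
                                    baseOnly = TRUE)[c("A", "C", "G", "T"), ,
                                                     drop = FALSE]
  cm <- sweep(cm, 2, colSums(cm), "/")   # renormalize if non-ACGT present
  colnames(cm) <- as.character(seq(-flank, flank))
  attr(cm, "n_sites") <- nrow(s)
  cm
}

#' Per-gene pause-site shift between conditions
#'
#' Signed difference of TSS offsets, `B - A` (positive = condition B
#' pause is downstream of condition A's). Genes missing in either
#' condition are excluded and counted.
#'
#' @param sites_a,sites_b Per-gene pause tables (see
#'   [top_pause_per_gene()]).
#' @return List: `shifts` (data.frame gene_id, shift), `median_shift`,
#'   `n_excluded`.
#' @export
pause_shift <- function(sites_a, sites_b) {
  common <- intersect(sites_a$gene_id, sites_b$gene_id)
  a <- sites_a[match(common, sites_a$gene_id), ]
  b <- sites_b[match(common, sites_b$gene_id), ]
  shifts <- data.frame(gene_id = common,
                       shift = b$offset_from_tss - a$offset_from_tss,
                       stringsAsFactors = FALSE)
  n_excl <- (nrow(sites_a) - length(common)) + (nrow(sites_b) - length(common))
  list(shifts = shifts,
       median_shift = if (nrow(shifts)) stats::median(shifts$shift) else NA_real_,
       n_excluded = n_excl)
}
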