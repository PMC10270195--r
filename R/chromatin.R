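#' Filter MNase fragments to the subnucleosomal size class
#'
#' Keeps fragments of length `target +/- tol` bp (default 58 +/- 5, i.e.
#' \[53, 63\]), the footprint of a partially unwrapped histone dyad half.
#' Idempotent.
#'
#' @param fragments Interval data frame of paired-end fragment spans.
#' @param target Target fragment length (default 58).
#' @param tol Tolerance in nt (default 5).
#' @return The subset of `fragments`.
#' @export
filter_fragments <- function(fragments, target = 58L, tol = 5L) {
  len <- fragments$end - fragments$start
  fragments[len >= target - tol & len <= target + tol, , drop = FALSE]
}

#' Call nucleosome centers from subnucleosomal fragment midpoints
#'
#' Fragment midpoints are smoothed with a Gaussian kernel (`smoothing_bw`
#' bp); local maxima supported by at least `min_support` raw midpoints
#' within +/-10 bp become dyad half-peaks. Two half-peaks 40-80 bp apart
#' on the same chromosome are paired into one nucleosome whose center is
#' the rounded mean; an unpaired half-peak yields a call with zero mass
#' on the missing side. Masses are the raw midpoint counts within
#' +/-14 bp of each half-peak, reported genomically as `mass_left` /
#' `mass_right` (orient against a gene strand with
#' [pause_nucleosome_distance()] / [minus1_nucleosomes()]).
#'
#' @param fragments Size-filtered fragment intervals.
#' @param smoothing_bw Gaussian kernel SD in bp (default 15).
#' @param min_support Minimum raw midpoints near a half-peak (default 10).
#' @return data.frame: `chrom`, `center`, `fragment_count`, `mass_left`,
#'   `mass_right`, `paired`.
#' @export
call_nucleosome_centers <- function(fragments, smoothing_bw = 15,
                                    min_support = 10L) {
  empty <- data.frame(chrom = character(), center = integer(),
                      fragment_count = integer(), mass_left = numeric(),
                      mass_right = numeric(), paired = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(fragments) == 0L) return(empty)
  mid <- as.integer(floor((fragments$start + fragments$end) / 2))
  out <- list()
  for (ch in unique(fragments$chrom)) {
    m <- mid[fragments$chrom == ch]
    lo <- min(m) - 3L * ceiling(smoothing_bw)
    hi <- max(m) + 3L * ceiling(smoothing_bw)
    counts <- tabulate(m - lo + 1L, nbins = hi - lo + 1L)
    kern_x <- seq(-3L * ceiling(smoothing_bw), 3L * ceiling(smoothing_bw))
    kern <- stats::dnorm(kern_x, sd = smoothing_bw)
    sm <- stats::filter(counts, kern, sides = 2)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm)
    n <- length(sm)
    is_max <- c(FALSE, sm[2:(n - 1)] >= sm[1:(n - 2)] &
                  sm[2:(n - 1)] >= sm[3:n] &
                  (sm[2:(n - 1)] > sm[1:(n - 2)] | sm[2:(n - 1)] > sm[3:n]),
                FALSE)
    peaks <- which(is_max) + lo - 1L
    if (!length(peaks)) next
    support <- vapply(peaks, function(p)
      sum(m >= p - 10L & m <= p + 10L), integer(1))
    keep <- support >= min_support
    peaks <- peaks[keep]
    support <- support[keep]
    if (!length(peaks)) next
    # thin plateaus/near-duplicate maxima within 20 bp, keep best support
    ord <- order(-support, peaks)
    sel <- logical(0)
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || all(abs(peaks[i] - peaks[kept]) > 20L))
        kept <- c(kept, i)
    }
    kept <- sort(kept)
    peaks <- peaks[kept]
    support <- support[kept]
    # pair half-peaks 40-80 bp apart, greedily by proximity to 58 bp
    used <- rep(FALSE, length(peaks))
    if (length(peaks) >= 2L) {
      cand <- which(outer(peaks, peaks, function(a, b) b - a) >= 40L &
                      outer(peaks, peaks, function(a, b) b - a) <= 80L,
                    arr.ind = TRUE)
      if (nrow(cand)) {
        sep <- peaks[cand[, 2]] - peaks[cand[, 1]]
        cand <- cand[order(abs(sep - 58L)), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (used[i] || used[j]) next
          used[i] <- used[j] <- TRUE
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch,
            center = as.integer(round((peaks[i] + peaks[j]) / 2)),
            fragment_count = support[i] + support[j],
            mass_left = half_mass(m, peaks[i]),
            mass_right = half_mass(m, peaks[j]),
            paired = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
    for (i in which(!used)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, center = peaks[i], fragment_count = support[i],
        mass_left = half_mass(m, peaks[i]), mass_right = 0,
        paired = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$center), , drop = FALSE]
}

half_mass <- function(midpoints, peak, halfwidth = 14L) {
  sum(midpoints >= peak - halfwidth & midpoints <= peak + halfwidth)
}

#' Identify -1 nucleosomes (TSS-overlapping calls)
#'
#' A nucleosome call is a -1 nucleosome when its canonical 147-bp
#' footprint `[center - 73, center + 74)` contains an annotated TSS.
#' Calls gain the matched `gene_id`, gene strand, and strand-oriented
#' proximal/distal dyad masses (distal = downstream of the center in the
#' direction of transcription).
#'
#' @param calls data.frame from [call_nucleosome_centers()].
#' @param genes A [gene_models()] object.
#' @return Subset of `calls` with columns `gene_id`, `strand`,
#'   `proximal_mass`, `distal_mass`, `overlaps_tss` added.
#' @export
minus1_nucleosomes <- function(calls, genes) {
  g <- genes$genes
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    foot_lo <- calls$center[i] - 73L
    foot_hi <- calls$center[i] + 73L   # inclusive; footprint [c-73, c+74)
    hit <- which(g$chrom == calls$chrom[i] & g$tss >= foot_lo &
                   g$tss <= foot_hi)
    for (h in hit) {
      r <- calls[i, , drop = FALSE]
      r$gene_id <- g$gene_id[h]
      r$strand <- g$strand[h]
      if (!r$paired) {
        # a lone half-peak is taken as the surviving (proximal) half
        r$proximal_mass <- r$mass_left + r$mass_right
        r$distal_mass <- 0
      } else if (g$strand[h] == "+") {
        r$proximal_mass <- r$mass_left
        r$distal_mass <- r$mass_right
      } else {
        r$proximal_mass <- r$mass_right
        r$distal_mass <- r$mass_left
      }
      r$overlaps_tss <- TRUE
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (!length(rows))
    return(cbind(calls[0, ], data.frame(gene_id = character(),
                                        strand = character(),
                                        proximal_mass = numeric(),
                                        distal_mass = numeric(),
                                        overlaps_tss = logical())))
  do.call(rbind, rows)
}

#' Strand-aware pause-to-nucleosome distance
#'
#' Signed distance in bp, positive when the pause lies downstream of the
#' nucleosome center in the direction of transcription.
#'
#' @param pause_position Pause position(s), 0-based.
#' @param center Nucleosome center(s).
#' @param strand Gene strand(s), `+` or `-`.
#' @return Integer vector of signed distances.
#' @export
pause_nucleosome_distance <- function(pause_position, center, strand) {
  as.integer(ifelse(strand == "+", pause_position - center,
                    center - pause_position))
}

#' Pause-distance cluster scheme
#'
#' The five distance bins used to stratify pauses by their distance
#' downstream of the -1 nucleosome center: cluster 1 = 80-120 bp,
#' 2 = 60-79, 3 = 40-59, 4 = 20-39, 5 = 0-19. Bins are disjoint,
#' inclusive-bound, and cover \[0, 120\].
#'
#' @return data.frame with `label`, `min_bp`, `max_bp`.
#' @export
cluster_scheme <- function() {
  data.frame(label = 1:5,
             min_bp = c(80L, 60L, 40L, 20L, 0L),
             max_bp = c(120L, 79L, 59L, 39L, 19L))
}

#' Assign pause-nucleosome distances to clusters
#'
#' Inclusive-bound bin lookup; distances outside \[0, 120\] (upstream
#' pauses or beyond the last bin) return `NA` (unassigned).
#'
#' @param distance Integer vector of signed distances.
#' @param scheme A [cluster_scheme()]-style data.frame.
#' @return Integer vector of cluster labels (NA = unassigned).
#' @export
assign_cluster <- function(distance, scheme = cluster_scheme()) {
  out <- rep(NA_integer_, length(distance))
  for (i in seq_len(nrow(scheme))) {
    inbin <- !is.na(distance) & distance >= scheme$min_bp[i] &
      distance <= scheme$max_bp[i]
    out[inbin] <- scheme$label[i]
  }
  out
}
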