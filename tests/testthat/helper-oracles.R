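# Independent oracles used across tests.

# Exact multinomial maximum tail P(max count >= c) for total reads
# dropped uniformly over width cells, by full enumeration of
# compositions (small total/width only).
exact_max_tail <- function(count, total, width) {
  prob_max_ge <- 0
  rec <- function(rem, cells, counts) {
    if (cells == 1L) {
      k <- c(counts, rem)
      if (max(k) >= count) {
        lp <- lgamma(total + 1) - sum(lgamma(k + 1)) - total * log(width)
        prob_max_ge <<- prob_max_ge + exp(lp)
      }
      return(invisible(NULL))
    }
    for (k in 0:rem) rec(rem - k, cells - 1L, c(counts, k))
  }
  rec(total, width, integer(0))
  prob_max_ge
}

# Brute-force two-sample KS statistic: sup |Fx - Fy| evaluated on the
# pooled sample points (ECDFs are constant between jumps).
ks_D_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
}

# Build an snt_signal from explicit per-position counts.
sig_from_counts <- function(chrom, strand, pos, count) {
  snt_signal(rep(chrom, length(pos)), rep(strand, length(pos)), pos, count)
}

# Minimal two-gene model set: one + gene and one - gene on chrT.
toy_genes <- function() {
  genes <- data.frame(
    gene_id = c("gP", "gM"),
    chrom = "chrT",
    strand = c("+", "-"),
    start = c(1000L, 20000L),
    end = c(6000L, 25000L))
  exons <- data.frame(
    gene_id = c("gP", "gM"),
    chrom = "chrT",
    start = c(1000L, 20000L),
    end = c(6000L, 25000L),
    strand = c("+", "-"))
  gene_models(genes, exons)
}

# Per-molecule truth signal: counts of unique molecules at unmasked
# positions, computed with plain arithmetic (independent of the
# package's masking/overlap code).
truth_signal_counts <- function(molecules, mask_df) {
  masked <- rep(FALSE, nrow(molecules))
  for (i in seq_len(nrow(mask_df))) {
    masked <- masked |
      (molecules$chrom == mask_df$chrom[i] &
         molecules$strand == mask_df$strand[i] &
         molecules$pos3 >= mask_df$start[i] &
         molecules$pos3 < mask_df$end[i])
  }
  m <- molecules[!masked, ]
  key <- paste(m$chrom, m$strand, m$pos3)
  tab <- table(key)
  data.frame(key = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
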