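#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: per-gene
#' single-nucleotide 3'-end signal with a sharp pause site 20-120 nt
#' downstream of the TSS plus uniform elongation signal, 8-bp UMIs with
#' PCR duplication, small-RNA/rRNA contaminant reads, subnucleosomal
#' 58-bp MNase fragments with a bimodal dyad structure, six-time-point
#' sinusoidal transcription, and two-tissue pause/body combinations.
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Min/max gene length in bp.
#' @param pause_offset_range Min/max pause offset downstream of the TSS
#'   (default 20-120 bp, the canonical promoter-proximal pausing zone).
#' @param pause_fraction Probability a nascent molecule is a pause read.
#' @param body_rate Expected reads per bp of gene body (used by
#'   [expected_molecules()] to size libraries).
#' @param umi_length UMI length in nt (default 8).
#' @param pcr_duplication_rate Mean extra PCR copies per molecule
#'   (Poisson).
#' @param contaminant_fraction Fraction of molecules from small-RNA loci.
#' @param rrna_fraction Fraction of molecules from rRNA loci.
#' @param read_length,insert_range Read and insert geometry in bp.
#' @param softclip_prob Probability read 2 carries a short (1-3 nt)
#'   5' soft clip (non-templated additions).
#' @param expression_sd SD of per-gene log-normal expression weights
#'   (0 = equal expression).
#' @param exons_per_gene_range Min/max exons per gene.
#' @param intergenic_gap Minimum gap between genes in bp (default 2000).
#' @param n_small_rna,n_rrna Number of contaminant loci.
#' @param plant_pause_motif Overwrite genome bases around each pause with
#'   a G/A (-1) / T/C (+1) initiator-like dinucleotide bias.
#' @param rhythmic_fraction Fraction of genes with rhythmic
#'   transcription; the non-rhythmic majority anchors cross-timepoint
#'   normalization, as in real tissue.
#' @param constitutive_pause_fraction Fraction of rhythmic genes whose
#'   pause signal stays constant across circadian timepoints (cycling
#'   body, stable promoter-proximal peak).
#' @param circadian_amplitude,circadian_phase Relative amplitude and peak
#'   phase (ZT hours) of sinusoidal transcription for rhythmic genes.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 100L,
                       gene_length_range = c(2000L, 6000L),
                       pause_offset_range = c(20L, 120L),
                       pause_fraction = 0.3,
                       body_rate = 0.025,
                       umi_length = 8L,
                       pcr_duplication_rate = 1,
                       contaminant_fraction = 0.05,
                       rrna_fraction = 0.05,
                       read_length = 50L,
                       insert_range = c(100L, 300L),
                       softclip_prob = 0.1,
                       expression_sd = 0.5,
                       exons_per_gene_range = c(1L, 3L),
                       intergenic_gap = 2000L,
                       n_small_rna = NULL,
                       n_rrna = 2L,
                       plant_pause_motif = TRUE,
                       rhythmic_fraction = 0.4,
                       constitutive_pause_fraction = 0.5,
                       circadian_amplitude = 0.9,
                       circadian_phase = 14,
                       seed = 1L) {
  if (is.null(n_small_rna)) n_small_rna <- max(2L, n_genes %/% 10L)
  cfg <- list(n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              pause_offset_range = as.integer(pause_offset_range),
              pause_fraction = pause_fraction,
              body_rate = body_rate,
              umi_length = as.integer(umi_length),
              pcr_duplication_rate = pcr_duplication_rate,
              contaminant_fraction = contaminant_fraction,
              rrna_fraction = rrna_fraction,
              read_length = as.integer(read_length),
              insert_range = as.integer(insert_range),
              softclip_prob = softclip_prob,
              expression_sd = expression_sd,
              exons_per_gene_range = as.integer(exons_per_gene_range),
              intergenic_gap = as.integer(intergenic_gap),
              n_small_rna = as.integer(n_small_rna),
              n_rrna = as.integer(n_rrna),
              plant_pause_motif = isTRUE(plant_pause_motif),
              rhythmic_fraction = rhythmic_fraction,
              constitutive_pause_fraction = constitutive_pause_fraction,
              circadian_amplitude = circadian_amplitude,
              circadian_phase = circadian_phase,
              seed = as.integer(seed))
  fr <- c(pause_fraction, contaminant_fraction, rrna_fraction,
          softclip_prob, rhythmic_fraction, constitutive_pause_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (contaminant_fraction + rrna_fraction >= 1)
    stop("contaminant fractions must sum to < 1")
  if (diff(cfg$gene_length_range) < 0 || diff(cfg$pause_offset_range) < 0 ||
      diff(cfg$insert_range) < 0)
    stop("ranges must be nondecreasing (min, max)")
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  if (cfg$pcr_duplication_rate < 0) stop("pcr_duplication_rate must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

random_umis <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# map transcription-local offsets (0 = TSS) to genomic positions
local_to_genomic <- function(tss, strand, offset) {
  ifelse(strand == "+", tss + offset, tss - offset)
}

#' Simulate a ground-truthed genome and annotation
#'
#' Places non-overlapping genes on two synthetic chromosomes with
#' intergenic gaps of at least `intergenic_gap`, assigns each gene 1-3
#' exons (the first transcribed exon always spans the pausing region),
#' a true pause position, a -1 nucleosome center, and circadian
#' parameters; small-RNA and rRNA loci go in intergenic space. The genome
#' sequence is random; by default, pause-adjacent bases get an
#' initiator-like G/A / T/C dinucleotide bias planted on the coding
#' strand.
#'
#' @param config A [sim_config()] object.
#' @return A `sim_truth` list: `annotation` ([annotation_set()]),
#'   `genome` (named character vector), `genes` (per-gene truth table
#'   with `pause_pos`, `pause_offset`, `expr_weight`, `nuc_center`,
#'   `constitutive_pause`, `amplitude`, `phase`), and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gap <- config$intergenic_gap

  lens <- if (n) as.integer(round(stats::runif(
    n, config$gene_length_range[1], config$gene_length_range[2]))) else integer(0)
  strands <- if (n) sample(c("+", "-"), n, replace = TRUE) else character(0)
  chroms <- if (n) rep(c("chrS1", "chrS2"), length.out = n) else character(0)

  genes <- vector("list", n)
  exons <- vector("list", n)
  cursor <- stats::setNames(rep(gap, 2L), c("chrS1", "chrS2"))
  for (i in seq_len(n)) {
    ch <- chroms[i]
    start <- cursor[[ch]]
    end <- start + lens[i]
    cursor[[ch]] <- end + gap + sample.int(2000L, 1L)
    strand <- strands[i]
    gid <- sprintf("gene%03d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                             start = start, end = end,
                             stringsAsFactors = FALSE)
    exons[[i]] <- make_exons(gid, ch, strand, start, end,
                             config$exons_per_gene_range)
  }
  gene_df <- if (n) do.call(rbind, genes) else
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), start = integer(), end = integer())
  exon_df <- if (n) do.call(rbind, exons) else
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character())
  gm <- gene_models(gene_df, exon_df)
  g <- gm$genes

  # truth: pause positions, expression, nucleosomes, circadian parameters
  off <- if (n) sample(seq(config$pause_offset_range[1],
                           config$pause_offset_range[2]), n,
                       replace = TRUE) else integer(0)
  pause_pos <- as.integer(local_to_genomic(g$tss, g$strand, off))
  w <- if (n) {
    if (config$expression_sd > 0)
      stats::rlnorm(n, 0, config$expression_sd) else rep(1, n)
  } else numeric(0)
  # -1 nucleosome center upstream of the pause by 0-120 bp (so pause
  # distances downstream of the center cover all cluster bins)
  nuc_d <- if (n) sample(0:120, n, replace = TRUE) else integer(0)
  nuc_center <- as.integer(local_to_genomic(pause_pos, g$strand, -nuc_d))
  rhythmic <- if (n) stats::runif(n) < config$rhythmic_fraction else logical(0)
  const_pause <- rhythmic &
    (if (n) stats::runif(n) < config$constitutive_pause_fraction else logical(0))
  truth_genes <- data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    tss = g$tss, tes = g$tes, length = lens,
    pause_pos = pause_pos, pause_offset = as.integer(off),
    expr_weight = if (n) w / sum(w) else numeric(0),
    nuc_center = nuc_center,
    rhythmic = rhythmic,
    constitutive_pause = const_pause,
    amplitude = ifelse(rhythmic, config$circadian_amplitude, 0),
    phase = rep(config$circadian_phase, n))

  # contaminant loci in intergenic space past the gene arrays
  sr <- place_loci(config$n_small_rna, cursor, gap, len_range = c(80L, 200L),
                   prefix = "smallRNA")
  cursor <- attr(sr, "cursor")
  rr <- place_loci(config$n_rrna, cursor, gap, len_range = c(1000L, 2000L),
                   prefix = "rRNA")
  cursor <- attr(rr, "cursor")

  chrom_sizes <- stats::setNames(as.integer(unlist(cursor) + gap),
                                 names(cursor))
  genome <- vapply(chrom_sizes, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))

  if (config$plant_pause_motif && n) {
    genome <- plant_motifs(genome, truth_genes)
  }

  ann <- annotation_set(gm, small_rna = sr, rrna = rr,
                        chrom_sizes = chrom_sizes)
  structure(list(annotation = ann, genome = genome, genes = truth_genes,
                 config = config), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d genes, %d small-RNA loci, %d rRNA loci, seed %d\n",
              nrow(x$genes), nrow(x$annotation$small_rna),
              nrow(x$annotation$rrna), x$config$seed))
  invisible(x)
}

# split a gene span into alternating exons/introns in transcription order;
# the first transcribed exon is >= 400 bp so the pausing region (<= 200 nt
# plus motif flanks) sits inside it, away from any masked exon 3' end
make_exons <- function(gid, chrom, strand, start, end, n_range) {
  L <- end - start
  n_ex <- sample(seq(n_range[1], n_range[2]), 1L)
  if (n_ex == 1L) {
    segs <- data.frame(a = 0L, b = L)
  } else {
    e1 <- max(400L, as.integer(L * 0.25))
    rest <- L - e1
    intron <- as.integer(rest * 0.2 / (n_ex - 1L))
    exon <- as.integer((rest - intron * (n_ex - 1L)) / (n_ex - 1L))
    a <- e1
    segs <- data.frame(a = 0L, b = e1)
    for (k in seq_len(n_ex - 1L)) {
      a <- a + intron
      b <- if (k == n_ex - 1L) L else a + exon
      segs <- rbind(segs, data.frame(a = a, b = b))
      a <- b
    }
  }
  # local [a, b) -> genomic
  if (strand == "+") {
    data.frame(gene_id = gid, chrom = chrom, start = start + segs$a,
               end = start + segs$b, strand = strand,
               stringsAsFactors = FALSE)
  } else {
    tss <- end - 1L
    df <- data.frame(gene_id = gid, chrom = chrom,
                     start = tss - segs$b + 1L, end = tss - segs$a + 1L,
                     strand = strand, stringsAsFactors = FALSE)
    df[order(df$start), ]
  }
}

place_loci <- function(n_loci, cursor, gap, len_range, prefix) {
  if (n_loci == 0L) {
    out <- genomic_intervals()
    attr(out, "cursor") <- cursor
    return(out)
  }
  chs <- rep(names(cursor), length.out = n_loci)
  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    ch <- chs[i]
    len <- sample(seq(len_range[1], len_range[2]), 1L)
    start <- cursor[[ch]]
    rows[[i]] <- data.frame(chrom = ch, start = start, end = start + len,
                            name = sprintf("%s%02d", prefix, i),
                            score = 0,
                            strand = sample(c("+", "-"), 1L),
                            stringsAsFactors = FALSE)
    cursor[[ch]] <- start + len + gap
  }
  out <- do.call(rbind, rows)
  attr(out, "cursor") <- cursor
  out
}

plant_motifs <- function(genome, truth_genes) {
  for (i in seq_len(nrow(truth_genes))) {
    ch <- truth_genes$chrom[i]
    p <- truth_genes$pause_pos[i]
    strand <- truth_genes$strand[i]
    b_m1 <- sample(c("G", "A", "C", "T"), 1L, prob = c(.6, .3, .05, .05))
    b_p1 <- sample(c("T", "C", "G", "A"), 1L, prob = c(.6, .3, .05, .05))
    if (strand == "+") {
      substr(genome[[ch]], p, p) <- b_m1          # -1 base (0-based p-1 -> 1-based p)
      substr(genome[[ch]], p + 2L, p + 2L) <- b_p1
    } else {
      rc <- c(A = "T", C = "G", G = "C", T = "A")
      substr(genome[[ch]], p + 2L, p + 2L) <- rc[[b_m1]]
      substr(genome[[ch]], p, p) <- rc[[b_p1]]
    }
  }
  genome
}

#' Expected library size for a target per-gene depth
#'
#' Convenience: number of molecules so each gene receives roughly
#' `reads_per_gene` nascent reads after accounting for contaminant
#' fractions (assumes equal expression).
#'
#' @param config A [sim_config()] object.
#' @param reads_per_gene Target nascent reads per gene.
#' @return Integer molecule count.
#' @export
expected_molecules <- function(config, reads_per_gene = 50) {
  clean <- 1 - config$contaminant_fraction - config$rrna_fraction
  as.integer(ceiling(config$n_genes * reads_per_gene / clean))
}

#' Simulate aligned nascent-RNA read pairs
#'
#' Draws molecules from the truth: with probability `pause_fraction` a
#' gene molecule's 3' end sits exactly at the gene's pause position,
#' otherwise uniformly over the body downstream of the pause; contaminant
#' molecules end within small-RNA/rRNA loci. Each molecule gets a random
#' UMI and is emitted `1 + Poisson(pcr_duplication_rate)` times with
#' identical coordinates and UMI. Read 2 is antisense to the nascent RNA
#' by default, its first sequenced base at the RNA 3' end; minus-strand
#' genes are handled mirror-symmetrically.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param n_molecules Number of unique molecules to draw.
#' @param seed Integer seed.
#' @return List with `pairs` (an `aligned_pairs` table, PCR duplicates
#'   included) and `molecules` (ground-truth table of distinct molecules;
#'   coincidentally identical molecules -- same chrom, strand, mate 5'
#'   ends and UMI -- are collapsed, since they are indistinguishable from
#'   PCR duplicates by construction).
#' @export
simulate_reads <- function(truth, n_molecules, seed = truth$config$seed) {
  stopifnot(inherits(truth, "sim_truth"), n_molecules >= 0)
  cfg <- truth$config
  set.seed(seed)
  n <- as.integer(n_molecules)
  if (n == 0L || nrow(truth$genes) == 0L) {
    return(list(pairs = empty_pairs(), molecules = empty_molecules()))
  }
  u <- stats::runif(n)
  cls <- ifelse(u < cfg$contaminant_fraction, "small_rna",
         ifelse(u < cfg$contaminant_fraction + cfg$rrna_fraction, "rrna",
                "gene"))
  tg <- truth$genes
  gi <- sample.int(nrow(tg), n, replace = TRUE, prob = tg$expr_weight)

  chrom <- tg$chrom[gi]
  strand <- tg$strand[gi]
  gene_id <- tg$gene_id[gi]
  is_pause <- stats::runif(n) < cfg$pause_fraction
  # 3' offset from TSS in transcription-local coordinates
  off3 <- ifelse(is_pause, tg$pause_offset[gi],
                 tg$pause_offset[gi] +
                   floor(stats::runif(n) *
                           (tg$length[gi] - tg$pause_offset[gi] - 1L)) + 1L)
  pos3 <- as.integer(local_to_genomic(tg$tss[gi], strand, off3))

  # contaminants overwrite gene assignment
  place_contaminant <- function(idx, loci) {
    if (!length(idx) || nrow(loci) == 0L) return(invisible(NULL))
    li <- sample.int(nrow(loci), length(idx), replace = TRUE)
    chrom[idx] <<- loci$chrom[li]
    strand[idx] <<- loci$strand[li]
    gene_id[idx] <<- loci$name[li]
    # 3' end anywhere in the locus, at least insert-room from its edge
    lo <- loci$start[li]; hi <- loci$end[li] - 1L
    pos3[idx] <<- as.integer(lo + floor(stats::runif(length(idx)) * (hi - lo + 1L)))
    is_pause[idx] <<- FALSE
    off3[idx] <<- NA_integer_
  }
  place_contaminant(which(cls == "small_rna"), truth$annotation$small_rna)
  place_contaminant(which(cls == "rrna"), truth$annotation$rrna)

  rna_len <- ifelse(is.na(off3),
                    as.integer(cfg$insert_range[1]),  # contaminants: full insert room
                    off3 + 1L)
  ins <- pmin(as.integer(round(stats::runif(
    n, cfg$insert_range[1], cfg$insert_range[2]))), rna_len)
  ins <- pmax(ins, 20L)
  l2 <- pmin(cfg$read_length, ins)
  l1 <- pmin(cfg$read_length, ins)

  plus <- strand == "+"
  # read 2 antisense to the RNA; its first sequenced base is the 3' end
  r2_start <- ifelse(plus, pos3 - l2 + 1L, pos3)
  r2_end <- ifelse(plus, pos3 + 1L, pos3 + l2)
  r2_strand <- ifelse(plus, "-", "+")
  r1_start <- ifelse(plus, pos3 - ins + 1L, pos3 + ins - l1)
  r1_end <- ifelse(plus, pos3 - ins + 1L + l1, pos3 + ins)
  r1_strand <- ifelse(plus, "+", "-")
  r1_start <- pmax(r1_start, 0L)

  umi <- random_umis(n, cfg$umi_length)
  clip <- ifelse(stats::runif(n) < cfg$softclip_prob,
                 sample(1:3, n, replace = TRUE), 0L)

  r1_5p <- ifelse(r1_strand == "+", r1_start, r1_end - 1L)
  r2_5p <- ifelse(r2_strand == "+", r2_start, r2_end - 1L)

  mol <- data.table::data.table(
    mol_id = seq_len(n), class = cls, gene_id = gene_id,
    chrom = chrom, strand = strand, pos3 = pos3,
    r1_start = as.integer(r1_start), r1_end = as.integer(r1_end),
    r1_strand = r1_strand,
    r2_start = as.integer(r2_start), r2_end = as.integer(r2_end),
    r2_strand = r2_strand,
    r1_5p = as.integer(r1_5p), r2_5p = as.integer(r2_5p),
    umi = umi, clip = as.integer(clip))

  # collapse molecules indistinguishable from PCR duplicates
  mol <- mol[!duplicated(mol[, c("chrom", "strand", "r1_5p", "r2_5p", "umi")])]

  copies <- 1L + stats::rpois(nrow(mol), cfg$pcr_duplication_rate)
  idx <- rep(seq_len(nrow(mol)), copies)
  dup_rank <- sequence(copies)
  pr <- mol[idx]
  pairs <- data.table::data.table(
    name = sprintf("m%d.%d_%s", pr$mol_id, dup_rank, pr$umi),
    umi = pr$umi, chrom = pr$chrom,
    r1_start = pr$r1_start, r1_end = pr$r1_end, r1_strand = pr$r1_strand,
    r2_start = pr$r2_start, r2_end = pr$r2_end, r2_strand = pr$r2_strand,
    r2_leading_softclip = pr$clip,
    r2_trailing_softclip = 0L,
    clips_stripped = FALSE)
  class(pairs) <- c("aligned_pairs", class(pairs))
  molecules <- mol[, c("mol_id", "class", "gene_id", "chrom", "strand",
                       "pos3", "r1_5p", "r2_5p", "umi")]
  list(pairs = pairs, molecules = molecules)
}

empty_molecules <- function() {
  data.table::data.table(mol_id = integer(), class = character(),
                         gene_id = character(), chrom = character(),
                         strand = character(), pos3 = integer(),
                         r1_5p = integer(), r2_5p = integer(),
                         umi = character())
}

#' Simulate subnucleosomal MNase fragments
#'
#' Fragments of length 58 +/- 5 bp (uniform) are centered on one of the
#' two dyad-half positions 29 bp either side of each truth nucleosome
#' center. The TSS-proximal half (upstream of the center w.r.t. the gene
#' strand) carries weight 1 and the TSS-distal half weight
#' `1 - dyad_loss`, so the distal/proximal mass ratio is `1 - dyad_loss`.
#'
#' @param truth A `sim_truth` with `nuc_center` per gene.
#' @param n_fragments Number of fragments.
#' @param dyad_loss Scalar or per-gene vector in \[0, 1\]: 0 gives two
#'   equal-mass midpoint modes, 1 a single proximal mode.
#' @param seed Integer seed.
#' @return Interval data frame of fragments (`name` = source gene).
#' @export
simulate_mnase <- function(truth, n_fragments, dyad_loss = 0,
                           seed = truth$config$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  tg <- truth$genes
  if (nrow(tg) == 0L || n_fragments == 0L) return(genomic_intervals())
  dl <- rep_len(dyad_loss, nrow(tg))
  if (any(dl < 0 | dl > 1)) stop("dyad_loss must be in [0, 1]")
  gi <- sample.int(nrow(tg), n_fragments, replace = TRUE)
  p_distal <- (1 - dl[gi]) / (2 - dl[gi])   # weights (1, 1 - dyad_loss)
  distal <- stats::runif(n_fragments) < p_distal
  sgn <- ifelse(tg$strand[gi] == "+", 1L, -1L)
  half <- tg$nuc_center[gi] + ifelse(distal, 29L, -29L) * sgn
  len <- sample(53:63, n_fragments, replace = TRUE)
  start <- as.integer(half - floor(len / 2))
  genomic_intervals(chrom = tg$chrom[gi], start = pmax(start, 0L),
                    end = pmax(start, 0L) + len,
                    name = tg$gene_id[gi], strand = ".")
}

#' Simulate a circadian time course of 3'-end signal
#'
#' Per gene and timepoint, the expected exonic read count follows
#' `baseline * (1 + amplitude * cos(2*pi*(t - phase)/24))` with Poisson
#' sampling, reads placed uniformly over exonic positions. A constant
#' low-rate intronic background (co-transcriptional signal that exon-only
#' quantification must exclude) is added. Pause-site signal cycles with
#' the gene except for constitutive-pause genes, whose pause counts stay
#' constant across timepoints.
#'
#' @param truth A `sim_truth`.
#' @param timepoints Numeric ZT hours (default `c(2,6,10,14,18,22)`).
#' @param baseline Expected exonic reads per gene at mesor.
#' @param pause_ratio Pause-site expected count as a fraction of
#'   `baseline`.
#' @param intron_rate Intronic background reads as a fraction of
#'   `baseline` (constant in time).
#' @param seed Integer seed.
#' @return Named list (names `"ZT<t>"`) of [snt_signal()] objects.
#' @export
simulate_timecourse <- function(truth, timepoints = c(2, 6, 10, 14, 18, 22),
                                baseline = 1000, pause_ratio = 0.5,
                                intron_rate = 0.2,
                                seed = truth$config$seed) {
  stopifnot(inherits(truth, "sim_truth"), length(timepoints) >= 2L)
  set.seed(seed)
  tg <- truth$genes
  ex <- truth$annotation$genes$exons
  out <- vector("list", length(timepoints))
  names(out) <- paste0("ZT", timepoints)
  base_g <- baseline * tg$expr_weight * nrow(tg)  # mean `baseline` per gene
  for (k in seq_along(timepoints)) {
    t <- timepoints[k]
    lam <- base_g * (1 + tg$amplitude * cos(2 * pi * (t - tg$phase) / 24))
    lam <- pmax(lam, 0)
    chunks <- vector("list", nrow(tg))
    for (i in seq_len(nrow(tg))) {
      exi <- ex[ex$gene_id == tg$gene_id[i], ]
      expos <- unlist(lapply(seq_len(nrow(exi)), function(j)
        seq.int(exi$start[j], exi$end[j] - 1L)))
      n_ex <- stats::rpois(1L, lam[i])
      ppos <- if (n_ex > 0L) sample(expos, n_ex, replace = TRUE) else integer(0)
      # intronic background, constant across timepoints
      gene_span <- seq.int(min(tg$tss[i], tg$tes[i]),
                           max(tg$tss[i], tg$tes[i]))
      intron_pos <- setdiff(gene_span, expos)
      n_in <- if (length(intron_pos))
        stats::rpois(1L, intron_rate * base_g[i]) else 0L
      ipos <- if (n_in > 0L) sample(intron_pos, n_in, replace = TRUE) else integer(0)
      # pause signal: constant for constitutive-pause genes, cycling otherwise
      lam_p <- if (tg$constitutive_pause[i]) pause_ratio * base_g[i]
               else pause_ratio * lam[i]
      n_p <- stats::rpois(1L, lam_p)
      all_pos <- c(ppos, ipos, rep(tg$pause_pos[i], n_p))
      if (length(all_pos))
        chunks[[i]] <- data.table::data.table(
          chrom = tg$chrom[i], strand = tg$strand[i],
          pos = as.integer(all_pos), count = 1)
    }
    dt <- data.table::rbindlist(chunks)
    out[[k]] <- if (nrow(dt)) snt_signal(dt$chrom, dt$strand, dt$pos, dt$count)
                else snt_signal()
  }
  out
}

#' Write a simulation to disk in standard formats
#'
#' Emits SAM (aligned pairs), FASTA (genome), GTF (gene models), BED
#' (small RNA, rRNA, exon 3' ends), chrom.sizes, the configuration as
#' YAML, and the ground truth as a JSON sidecar.
#'
#' @param truth A `sim_truth`.
#' @param reads Result of [simulate_reads()] (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, reads = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- truth$annotation
  write_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_gtf(ann$genes, file.path(dir, "genes.gtf"))
  write_bed(ann$small_rna, file.path(dir, "small_rna.bed"))
  write_bed(ann$rrna, file.path(dir, "rrna.bed"))
  write_bed(ann$exon_three_prime_ends, file.path(dir, "exon3p.bed"))
  write_chrom_sizes(ann$chrom_sizes, file.path(dir, "chrom.sizes"))
  yaml::write_yaml(unclass(truth$config), file.path(dir, "sim_config.yaml"))
  jsonlite::write_json(truth$genes, file.path(dir, "truth_genes.json"),
                       dataframe = "rows", digits = NA)
  if (!is.null(reads)) {
    write_sam(reads$pairs, ann$chrom_sizes, file.path(dir, "reads.sam"))
    jsonlite::write_json(reads$molecules, file.path(dir, "truth_molecules.json"),
                         dataframe = "rows", digits = NA)
  }
  invisible(dir)
}
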