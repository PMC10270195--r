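make_pair <- function(name = "r_AAAAAAAA", chrom = "chrT",
                      r1 = c(100L, 150L), r1s = "+",
                      r2 = c(200L, 250L), r2s = "-",
                      lead = 0L, trail = 0L) {
  dt <- data.table::data.table(
    name = name, umi = sub(".*_", "", name), chrom = chrom,
    r1_start = r1[1], r1_end = r1[2], r1_strand = r1s,
    r2_start = r2[1], r2_end = r2[2], r2_strand = r2s,
    r2_leading_softclip = lead, r2_trailing_softclip = trail,
    clips_stripped = FALSE)
  class(dt) <- c("aligned_pairs", class(dt))
  dt
}

test_that("strip_softclips zeroes clip fields without moving the span", {
  p <- make_pair(lead = 3L)
  s <- strip_softclips(p)
  expect_equal(s$r2_start, p$r2_start)   # clips never consume reference
  expect_equal(s$r2_end, p$r2_end)
  expect_equal(s$r2_leading_softclip, 0L)
  expect_true(s$clips_stripped)
  # identity on clip-free pairs (other than the flag)
  p0 <- make_pair()
  s0 <- strip_softclips(p0)
  expect_equal(s0$r2_start, p0$r2_start)
  # degenerate fully clipped read dropped with warning
  bad <- make_pair(r2 = c(300L, 300L))
  expect_warning(out <- strip_softclips(rbind(p, bad)), "fully clipped")
  expect_equal(nrow(out), 1L)
})

test_that("deduplicate keeps one representative per exact key", {
  a <- make_pair("x_AAAAAAAA")
  b <- make_pair("y_AAAAAAAA")             # same key, different name
  c2 <- make_pair("z_AAAAAAAT")            # UMI differs by 1 nt: kept
  dd <- deduplicate(rbind(a, b, c2), verbose = FALSE)
  expect_equal(dd$kept, 2L)
  expect_equal(dd$removed, 1L)
  expect_equal(dd$pairs$name, c("x_AAAAAAAA", "z_AAAAAAAT"))  # first wins
  # idempotent
  dd2 <- deduplicate(dd$pairs, verbose = FALSE)
  expect_equal(dd2$removed, 0L)
  expect_equal(as.data.frame(dd2$pairs), as.data.frame(dd$pairs))
})

test_that("dedup on simulated reads recovers distinct molecules exactly", {
  cfg <- sim_config(n_genes = 30, pcr_duplication_rate = 1,
                    expression_sd = 0, seed = 7)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 1e4, seed = 8)
  dd <- deduplicate(reads$pairs, verbose = FALSE)
  expect_equal(dd$kept, nrow(reads$molecules))
})

test_that("single-nucleotide conversion anchors read 2's first base", {
  # read 2 maps +: position = r2_start; RNA strand flips by default
  p <- make_pair(r2 = c(1000L, 1050L), r2s = "+")
  s <- to_single_nucleotide(p)
  expect_equal(s$pos, 1000L)
  expect_equal(s$strand, "-")
  # read 2 maps -: position = r2_end - 1 (last base in sequencing order)
  m <- make_pair(r2 = c(1000L, 1050L), r2s = "-")
  sm <- to_single_nucleotide(m)
  expect_equal(sm$pos, 1049L)
  expect_equal(sm$strand, "+")
  # read2_sense flag keeps the mapping strand
  expect_equal(to_single_nucleotide(p, read2_sense = TRUE)$strand, "+")
})

test_that("conversion recovers simulated 3' ends with zero error", {
  cfg <- sim_config(n_genes = 40, pcr_duplication_rate = 0,
                    contaminant_fraction = 0, rrna_fraction = 0,
                    expression_sd = 0, seed = 17)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 5000, seed = 18)
  sig <- to_single_nucleotide(strip_softclips(reads$pairs))
  mol <- reads$molecules
  want <- snt_signal(mol$chrom, mol$strand, mol$pos3, rep(1, nrow(mol)))
  expect_equal(as.data.frame(sig), as.data.frame(want))
  # total signal conservation
  expect_equal(total_signal(sig), nrow(mol))
})

test_that("contaminant masking is strand-matched and boundary-exact", {
  gm <- toy_genes()
  mask <- genomic_intervals("chrT", 500L, 520L, strand = "+", name = "sno")
  ann <- annotation_set(gm, small_rna = mask,
                        exon_three_prime_ends = genomic_intervals())
  s <- sig_from_counts("chrT", "+", c(499L, 500L, 519L, 520L), c(1, 2, 3, 4))
  out <- mask_contaminants(s, ann, verbose = FALSE)
  # half-open: 500 and 519 removed, 499 and 520 kept
  expect_equal(out$pos, c(499L, 520L))
  # opposite strand untouched
  sm <- sig_from_counts("chrT", "-", 510L, 5)
  expect_equal(nrow(mask_contaminants(sm, ann, verbose = FALSE)), 1L)
  # empty mask is the identity
  ann0 <- annotation_set(gm, exon_three_prime_ends = genomic_intervals())
  expect_equal(as.data.frame(mask_contaminants(s, ann0, verbose = FALSE)),
               as.data.frame(s))
})

test_that("contamination report converges to simulated fractions", {
  cfg <- sim_config(n_genes = 50, contaminant_fraction = 0.4,
                    rrna_fraction = 0.05, pcr_duplication_rate = 0,
                    expression_sd = 0, seed = 27)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 1e5, seed = 28)
  sig <- to_single_nucleotide(reads$pairs)
  rep <- contamination_report(sig, truth$annotation)
  expect_equal(rep$small_rna_fraction, 0.4, tolerance = 0.025)
  expect_equal(rep$rrna_fraction, 0.05, tolerance = 0.2)
  # degenerate cases
  allr <- sig_from_counts(truth$annotation$rrna$chrom[1],
                          truth$annotation$rrna$strand[1],
                          truth$annotation$rrna$start[1] + 1L, 10)
  expect_equal(contamination_report(allr, truth$annotation)$rrna_fraction, 1)
})

test_that("TSS windows are strand-mirrored and merged when overlapping", {
  genes <- data.frame(gene_id = c("a", "b", "m"), chrom = "chrT",
                      strand = c("+", "+", "-"),
                      start = c(0L, 100L, 100L), end = c(1000L, 1100L, 501L))
  exons <- data.frame(gene_id = genes$gene_id, chrom = "chrT",
                      start = genes$start, end = genes$end,
                      strand = genes$strand)
  gm <- gene_models(genes, exons)
  win <- tss_windows(gm, size = 200L)
  plus <- win[win$strand == "+", ]
  # two + genes 100 apart merge to one region owning both
  expect_equal(nrow(plus), 1L)
  expect_equal(c(plus$start, plus$end), c(0L, 300L))
  expect_equal(plus$gene_ids, "a,b")
  # minus gene at tss = 500: window (300, 500] -> internal [301, 501)
  minus <- win[win$strand == "-", ]
  expect_equal(c(minus$start, minus$end), c(301L, 501L))
  # restriction keeps exactly in-window positions
  s <- sig_from_counts("chrT", "-", c(300L, 301L, 500L, 501L), c(1, 1, 1, 1))
  r <- restrict_to_tss_windows(s, gm, window = 200L)
  expect_equal(r$signal$pos, c(301L, 500L))
})
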