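site_row <- function(gene, pos, count, offset) {
  data.frame(gene_id = gene, chrom = "chrT", strand = "+", position = pos,
             count = count, p_value = 1e-9, offset_from_tss = offset,
             stringsAsFactors = FALSE)
}

test_that("merge_pause_peaks picks the larger peak and tags provenance", {
  a <- rbind(site_row("g1", 150L, 30, 50L), site_row("g2", 250L, 12, 50L),
             site_row("g3", 350L, 9, 50L))
  b <- rbind(site_row("g1", 150L, 20, 50L), site_row("g2", 260L, 30, 60L),
             site_row("g4", 450L, 7, 50L))
  m <- merge_pause_peaks(a, b)
  expect_equal(m$position[m$gene_id == "g1"], 150L)
  expect_equal(m$provenance[m$gene_id == "g1"], "both")
  # counts 12 vs 30 at different positions: keep the 30
  expect_equal(m$position[m$gene_id == "g2"], 260L)
  expect_equal(m$provenance[m$gene_id == "g3"], "A_only")
  expect_equal(m$provenance[m$gene_id == "g4"], "B_only")
  # count tie at different offsets: TSS-proximal wins
  t1 <- merge_pause_peaks(site_row("g", 160L, 10, 60L),
                          site_row("g", 140L, 10, 40L))
  expect_equal(t1$position, 140L)
})

test_that("identical conditions classify every gene as (same, same)", {
  cfg <- sim_config(n_genes = 40, expression_sd = 0, seed = 81)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 8000, seed = 82)
  pp <- preprocess_pairs(reads$pairs, truth$annotation, verbose = FALSE)
  top <- top_pause_per_gene(
    detect_pauses(pp$signal, truth$annotation$genes, seed = 83))
  anchors <- merge_pause_peaks(top, top)
  res <- concordance_classify(pp$signal, pp$signal, anchors,
                              truth$annotation$genes)
  expect_true(all(res$records$pause_class == "same"))
  expect_true(all(res$records$body_class == "same"))
  expect_equal(unname(res$fractions["concordant"]), 1)
  expect_equal(sum(res$grid), nrow(res$records))
  # grid fractions sum to 1
  expect_equal(sum(res$fractions[c("concordant", "single_discordant",
                                   "double_discordant")]), 1)
})

test_that("fc_threshold 1 leaves no room for 'same' unless exactly equal", {
  cfg <- sim_config(n_genes = 20, expression_sd = 0, seed = 85)
  truth <- simulate_genome(cfg)
  reads_a <- simulate_reads(truth, 4000, seed = 86)
  reads_b <- simulate_reads(truth, 4000, seed = 87)
  pa <- preprocess_pairs(reads_a$pairs, truth$annotation, verbose = FALSE)
  pb <- preprocess_pairs(reads_b$pairs, truth$annotation, verbose = FALSE)
  top <- top_pause_per_gene(
    detect_pauses(pa$signal, truth$annotation$genes, seed = 88))
  anchors <- merge_pause_peaks(top, top)
  res <- concordance_classify(pa$signal, pb$signal, anchors,
                              truth$annotation$genes,
                              factors = c(1, 1), fc_threshold = 1)
  same <- res$records$pause_class == "same"
  # with threshold 1, 'same' requires a ratio of exactly 1 twice over
  expect_true(mean(same) < 0.5)
})

test_that("antisymmetry: swapping conditions transposes the classes", {
  cfg <- sim_config(n_genes = 30, expression_sd = 0, seed = 91)
  truth <- simulate_genome(cfg)
  ra <- simulate_reads(truth, 6000, seed = 92)
  rb <- simulate_reads(truth, 3000, seed = 93)   # B shallower
  pa <- preprocess_pairs(ra$pairs, truth$annotation, verbose = FALSE)
  pb <- preprocess_pairs(rb$pairs, truth$annotation, verbose = FALSE)
  top <- top_pause_per_gene(
    detect_pauses(pa$signal, truth$annotation$genes, seed = 94))
  anchors <- merge_pause_peaks(top, top)
  f <- c(1, 1)
  ab <- concordance_classify(pa$signal, pb$signal, anchors,
                             truth$annotation$genes, factors = f)
  ba <- concordance_classify(pb$signal, pa$signal, anchors,
                             truth$annotation$genes, factors = f)
  flip <- function(x) factor(ifelse(x == "A_higher", "B_higher",
                             ifelse(x == "B_higher", "A_higher", "same")),
                             levels = levels(x))
  expect_equal(as.character(ba$records$pause_class),
               as.character(flip(ab$records$pause_class)))
  expect_equal(as.character(ba$records$body_class),
               as.character(flip(ab$records$body_class)))
})

test_that("circadian quantification is exon-only and matrix ops behave", {
  genes <- data.frame(gene_id = "g", chrom = "chrT", strand = "+",
                      start = 100L, end = 1100L)
  exons <- data.frame(gene_id = c("g", "g"), chrom = "chrT",
                      start = c(100L, 700L), end = c(400L, 1100L),
                      strand = "+")
  gm <- gene_models(genes, exons)
  # intronic spike at 500 contributes nothing; exonic positions count
  s1 <- sig_from_counts("chrT", "+", c(200L, 500L), c(10, 99))
  s2 <- sig_from_counts("chrT", "+", c(200L, 800L), c(10, 30))
  mat <- circadian_quantify(list(ZT2 = s1, ZT14 = s2), gm, normalize = FALSE)
  expect_equal(unname(mat["g", ]), c(10, 40))
  # consistency with quantify() summed over exons
  ex_reg <- genomic_intervals(exons$chrom, exons$start, exons$end,
                              strand = exons$strand)
  expect_equal(unname(mat["g", "ZT14"]), sum(quantify(s2, ex_reg)))

  # normalize_to_peak: arithmetic, idempotence, zero-row dropping
  m <- rbind(a = c(10, 20, 50, 40, 20, 10), b = c(3, 3, 3, 3, 3, 3),
             z = c(0, 0, 0, 0, 0, 0))
  colnames(m) <- paste0("ZT", c(2, 6, 10, 14, 18, 22))
  expect_message(n1 <- normalize_to_peak(m), "all-zero")
  expect_equal(unname(n1["a", ]), c(0.2, 0.4, 1.0, 0.8, 0.4, 0.2))
  expect_equal(unname(n1["b", ]), rep(1, 6))
  expect_false("z" %in% rownames(n1))
  expect_equal(normalize_to_peak(n1), n1)
  pt <- peak_trough(n1)
  expect_equal(pt$peak[pt$gene_id == "a"], "ZT10")
  expect_equal(pt$amplitude[pt$gene_id == "b"], 1)   # flat gene
  # infinite amplitude flag when the trough is 0
  m2 <- rbind(g = c(0, 5, 10, 5, 1, 1))
  colnames(m2) <- colnames(m)
  expect_true(peak_trough(m2)$infinite_amplitude)
})
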