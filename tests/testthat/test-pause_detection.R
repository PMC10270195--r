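test_that("bootstrap p-value converges to the exact multinomial tail", {
  set.seed(99)
  cases <- list(c(3, 4, 3), c(2, 4, 6), c(3, 8, 6), c(4, 8, 6), c(3, 6, 2))
  for (cs in cases) {
    c0 <- cs[1]; T0 <- cs[2]; W0 <- cs[3]
    p_exact <- exact_max_tail(c0, T0, W0)
    se <- sqrt(max(p_exact * (1 - p_exact), 0) / 2e4)
    p_boot <- pause_null_pvalue(c0, T0, W0, n_boot = 2e4)
    expect_lt(abs(p_boot - p_exact), 3 * se + 2 / 2e4)
  }
})

test_that("analytic fallback reports sub-floor p for extreme spikes", {
  # a spike carrying the whole window total: bootstrap can never see
  # k = 0 counterexamples... the exceedance count is n_boot (max == c),
  # so use a spike much larger than the uniform-null maximum
  p <- pause_null_pvalue(50, 55, 100, n_boot = 1000)
  expect_lt(p, 1e-5)
  # and it is bounded by the Bonferroni tail
  expect_lte(p, 100 * pbinom(49, 55, 0.01, lower.tail = FALSE))
})

test_that("detect_pauses calls planted spikes and ignores uniform noise", {
  gm <- toy_genes()
  # uniform count-1 signal: fails min_intensity, no calls
  s_unif <- sig_from_counts("chrT", "+", 1000:1199, rep(1, 200))
  expect_equal(nrow(detect_pauses(s_unif, gm, seed = 1)), 0L)

  # single 50-read spike, window otherwise empty: called at exact base
  s_spike <- sig_from_counts("chrT", "+", 1050L, 50)
  hits <- detect_pauses(s_spike, gm, seed = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 1050L)
  expect_equal(hits$gene_id, "gP")
  expect_equal(hits$offset_from_tss, 50L)
  expect_lt(hits$p_value, 1e-5)

  # spike of 5 on a dense uniform background (~5/position): not called
  set.seed(4)
  bg <- sig_from_counts("chrT", "+", 1000:1199, rep(5, 200))
  hits_bg <- detect_pauses(bg, gm, pda_params(), seed = 2)
  expect_equal(nrow(hits_bg), 0L)

  # minus-strand gene: offsets measured toward decreasing coordinates
  s_m <- sig_from_counts("chrT", "-", 24999L - 60L, 40)
  hm <- detect_pauses(s_m, gm, seed = 3)
  expect_equal(hm$gene_id, "gM")
  expect_equal(hm$offset_from_tss, 60L)
})

test_that("detection is deterministic and monotone in its thresholds", {
  cfg <- sim_config(n_genes = 30, expression_sd = 0, seed = 51)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 6000, seed = 52)
  pp <- preprocess_pairs(reads$pairs, truth$annotation, verbose = FALSE)
  h1 <- detect_pauses(pp$signal, truth$annotation$genes, seed = 7)
  h2 <- detect_pauses(pp$signal, truth$annotation$genes, seed = 7)
  expect_identical(h1, h2)
  # raising min_intensity or tightening p never adds sites
  h_str <- detect_pauses(pp$signal, truth$annotation$genes,
                         pda_params(min_intensity = 20L), seed = 7)
  expect_true(all(h_str$position %in% h1$position))
  h_p <- detect_pauses(pp$signal, truth$annotation$genes,
                       pda_params(p_threshold = 1e-9), seed = 7)
  expect_true(all(h_p$position %in% h1$position))
  expect_lte(nrow(h_p), nrow(h1))
})

test_that("top_pause_per_gene keeps the highest count, ties TSS-proximal", {
  sites <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    chrom = "c", strand = "+",
    position = c(130L, 160L, 230L, 260L, 330L),
    count = c(10, 7, 10, 10, 4),
    p_value = 1e-6,
    offset_from_tss = c(30L, 60L, 30L, 60L, 30L))
  top <- top_pause_per_gene(sites)
  expect_equal(top$count[top$gene_id == "g1"], 10)
  expect_equal(top$offset_from_tss[top$gene_id == "g2"], 30L)  # tie rule
  expect_equal(nrow(top), 3L)
})

test_that("pause motifs recover the planted -1/+1 dinucleotide bias", {
  cfg <- sim_config(n_genes = 60, expression_sd = 0,
                    pcr_duplication_rate = 0, seed = 61)
  truth <- simulate_genome(cfg)
  reads <- simulate_reads(truth, 12000, seed = 62)
  pp <- preprocess_pairs(reads$pairs, truth$annotation, verbose = FALSE)
  top <- top_pause_per_gene(
    detect_pauses(pp$signal, truth$annotation$genes, seed = 63))
  pfm <- extract_pause_motif(top, truth$genome, flank = 10)
  expect_equal(dim(pfm), c(4L, 21L))
  expect_true(all(abs(colSums(pfm) - 1) < 1e-9))
  # planted G/A at -1 and T/C at +1 dominate
  expect_gt(sum(pfm[c("G", "A"), "-1"]), 0.75)
  expect_gt(sum(pfm[c("T", "C"), "1"]), 0.75)
  # identical sequences give unit columns
  one <- data.frame(gene_id = "g", chrom = names(truth$genome)[1],
                    strand = "+", position = 100L, count = 10,
                    p_value = 1e-9, offset_from_tss = 10L)
  pfm1 <- extract_pause_motif(rbind(one, one, one), truth$genome)
  expect_true(all(apply(pfm1, 2, max) == 1))
  # missing chromosome errors
  expect_error(extract_pause_motif(
    data.frame(gene_id = "g", chrom = "nope", strand = "+", position = 5L,
               count = 1, p_value = 1, offset_from_tss = 1L),
    truth$genome), "missing")
})

test_that("pause_shift reports signed per-gene offset differences", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c", strand = "+",
                  position = c(150L, 250L, 350L), count = 10, p_value = 1e-6,
                  offset_from_tss = c(50L, 50L, 50L))
  expect_equal(pause_shift(a, a)$median_shift, 0)
  b <- a
  b$offset_from_tss <- b$offset_from_tss - 20L
  expect_equal(pause_shift(a, b)$median_shift, -20)
  # genes missing in one condition are excluded and counted
  res <- pause_shift(a, b[1:2, ])
  expect_equal(nrow(res$shifts), 2L)
  expect_equal(res$n_excluded, 1L)
})
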