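test_that("quantify sums strand-matched signal with half-open bounds", {
  s <- sig_from_counts("chrT", "+", c(100L, 150L, 199L, 200L), c(1, 2, 3, 4))
  reg <- genomic_intervals("chrT", 100L, 200L, strand = "+")
  expect_equal(quantify(s, reg), 6)           # 200 excluded
  expect_equal(quantify(snt_signal(), reg), 0)
  # unstranded region matches both strands
  sm <- sig_from_counts("chrT", "-", 150L, 10)
  reg0 <- genomic_intervals("chrT", 100L, 200L, strand = ".")
  expect_equal(quantify(rbind(s, sm), reg0), 16)
  # wrong strand contributes nothing
  regm <- genomic_intervals("chrT", 100L, 200L, strand = "-")
  expect_equal(quantify(s, regm), 0)
})

test_that("anchored pausing index follows the density-ratio definition", {
  gm <- toy_genes()
  gene <- gm$genes[gm$genes$gene_id == "gP", ]
  pause <- data.frame(gene_id = "gP", chrom = "chrT", strand = "+",
                      position = 1049L, count = 50, p_value = 1e-9,
                      offset_from_tss = 49L)
  # 100 reads in the 50-bp pause region, 200 in the 1000-bp body
  s <- snt_signal(rep("chrT", 2), rep("+", 2), c(1020L, 1500L), c(100, 200))
  rec <- pausing_index_anchored(gene, pause, s)
  expect_equal(rec$pause_length, 50L)
  expect_equal(rec$index, (100 / 50) / (200 / 1000))  # = 10
  # uniform signal gives index 1
  su <- sig_from_counts("chrT", "+", 1000:2049, rep(2, 1050))
  expect_equal(pausing_index_anchored(gene, pause, su)$index, 1)
  # zero body signal is flagged, not divided
  s0 <- sig_from_counts("chrT", "+", 1010L, 100)
  rec0 <- pausing_index_anchored(gene, pause, s0)
  expect_false(rec0$ok)
  expect_true(is.na(rec0$index))
  # body truncation at the TES warns
  pauseLate <- pause; pauseLate$position <- 5500L
  pauseLate$offset_from_tss <- 4500L
  expect_warning(pausing_index_anchored(gene, pauseLate, su), "truncated")
  # raw ratio mode
  rec_raw <- pausing_index_anchored(gene, pause, s, raw_ratio = TRUE)
  expect_equal(rec_raw$index, 0.5)
})

test_that("fixed and anchored indices agree in the constructed case", {
  # pause at +200 with body_length = remaining gene body makes the two
  # definitions coincide (upstream window empty)
  genes <- data.frame(gene_id = "g", chrom = "chrT", strand = "+",
                      start = 1000L, end = 2450L)
  exons <- data.frame(gene_id = "g", chrom = "chrT", start = 1000L,
                      end = 2450L, strand = "+")
  gm <- gene_models(genes, exons)
  gene <- gm$genes[1, ]
  set.seed(8)
  pos <- sample(1000:2449, 300, replace = TRUE)
  s <- snt_signal(rep("chrT", 300), rep("+", 300), pos, rep(1, 300))
  pause <- data.frame(gene_id = "g", chrom = "chrT", strand = "+",
                      position = 1199L, count = 5, p_value = 1e-9,
                      offset_from_tss = 199L)
  anc <- pausing_index_anchored(gene, pause, s, body_length = 1250L)
  suppressWarnings(fix <- pausing_index_fixed(gene, s))
  # fixed promoter [tss-50, tss+200) has no upstream signal here, so the
  # numerators differ only by the 50-bp length denominator
  expect_equal(anc$pause_signal, fix$pause_signal)
  expect_equal(anc$body_signal, fix$body_signal)
  expect_equal(anc$index / fix$index,
               (anc$body_length / anc$pause_length) /
                 (fix$body_length / fix$pause_length))
  # minus-strand fixed index on uniform signal is 1
  gmM <- toy_genes()
  geneM <- gmM$genes[gmM$genes$gene_id == "gM", ]
  # uniform signal covering the upstream promoter flank too
  sU <- sig_from_counts("chrT", "-", 20000:25049, rep(3, 5050))
  expect_equal(pausing_index_fixed(geneM, sU)$index, 1, tolerance = 1e-12)
})

test_that("KS statistic matches the brute-force ECDF oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  set.seed(123)
  for (i in 1:100) {
    nx <- sample(2:50, 1); ny <- sample(2:50, 1)
    x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(x, y)$D, ks_D_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("median-of-ratios factors match hand computation and DESeq2", {
  # identical columns give unit factors
  m <- matrix(c(3, 7, 9, 3, 7, 9), ncol = 2)
  expect_equal(unname(size_factors(m)), c(1, 1))
  # hand example: reference = geometric means (sqrt(8), sqrt(32)),
  # ratios per column are 1/sqrt(2) and sqrt(2)
  m2 <- matrix(c(2, 2, 4, 4), ncol = 2)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # rows containing zeros are excluded from the reference set
  m3 <- rbind(m2, c(0, 5))
  expect_equal(unname(size_factors(m3)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # no all-positive feature errors
  expect_error(size_factors(matrix(c(0, 1, 1, 0), ncol = 2)), "all-positive")
  # independent cross-check against the reference implementation
  set.seed(42)
  cnt <- matrix(rpois(2000, lambda = rep(exp(rnorm(500, 4, 1)), 4) *
                        rep(c(0.6, 1, 1.4, 1.9), each = 500)),
                ncol = 4)
  f_ours <- unname(size_factors(cnt))
  f_ref <- unname(DESeq2::estimateSizeFactorsForMatrix(cnt))
  expect_equal(f_ours, f_ref, tolerance = 1e-6)
})

test_that("normalize_signal scales exactly and composes", {
  s <- sig_from_counts("chrT", "+", 1:10, rep(4, 10))
  expect_equal(as.data.frame(normalize_signal(s, 1)), as.data.frame(s))
  expect_equal(total_signal(normalize_signal(s, 2)), total_signal(s) / 2)
  ab <- normalize_signal(normalize_signal(s, 2), 3)
  expect_equal(as.data.frame(ab), as.data.frame(normalize_signal(s, 6)))
  expect_error(normalize_signal(s, 0), "positive")
  # pausing index is invariant to global library scaling
  gm <- toy_genes()
  gene <- gm$genes[1, ]
  pause <- data.frame(gene_id = "gP", chrom = "chrT", strand = "+",
                      position = 1049L, count = 50, p_value = 1e-9,
                      offset_from_tss = 49L)
  sU <- sig_from_counts("chrT", "+", 1000:2100, rpois(1101, 3) + 1)
  i1 <- pausing_index_anchored(gene, pause, sU)$index
  i2 <- pausing_index_anchored(gene, pause, normalize_signal(sU, 2.7))$index
  expect_equal(i1, i2, tolerance = 1e-12)
})
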