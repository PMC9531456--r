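# Small worlds keep these fast; the full default world is exercised by
# the acceptance suite.
small_cfg <- function(...) {
  args <- list(n_chroms = 2L, chrom_length = 4e5, n_genes = 16L,
               n_dels = 24L, seed = 11L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(synthetic_config, args)
}

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(g1$truth$occupancy, g2$truth$occupancy)
  t1 <- simulate_coverage(g1$annotation, g1$truth, "H3K18la", "tissue1", cfg)
  t2 <- simulate_coverage(g2$annotation, g2$truth, "H3K18la", "tissue1", cfg)
  expect_identical(t1$data, t2$data)
  e1 <- simulate_expression(g1$annotation, g1$truth, "tissue1", cfg)
  e2 <- simulate_expression(g2$annotation, g2$truth, "tissue1", cfg)
  expect_identical(e1, e2)
  # different seed changes the draw
  g3 <- generate_genome(small_cfg(seed = 12L))
  expect_false(identical(g1$truth$occupancy, g3$truth$occupancy))
})

test_that("element classes respect the TSS-distance definitions", {
  cfg <- synthetic_config(n_genes = 3L, n_chroms = 1L,
                          chrom_length = 1e5, n_dels = 4L, seed = 2L)
  g <- generate_genome(cfg)
  tss <- g$annotation$genes$tss
  dels <- g$truth$elements[class %in% c("dELS_shared",
                                        "dELS_tissue_specific")]
  for (i in seq_len(nrow(dels))) {
    d <- pmin(abs(dels$start[i] - tss), abs(dels$end[i] - tss))
    expect_gt(min(d), 2000)
  }
  pels <- g$truth$elements[class == "pELS"]
  gid <- match(pels$gene_id, g$annotation$genes$gene_id)
  edge <- pmin(abs(pels$start - tss[gid]), abs(pels$end - tss[gid]))
  expect_true(all(edge <= 2000))
  pls <- g$truth$elements[class == "PLS"]
  gid <- match(pls$gene_id, g$annotation$genes$gene_id)
  expect_true(all(pls$start >= tss[gid] - 200 & pls$end <= tss[gid] + 200))
})

test_that("degenerate fractions behave as stated", {
  g <- generate_genome(small_cfg(frac_housekeeping = 1))
  expect_true(all(g$annotation$genes$housekeeping))
  prom <- g$truth$elements[class %in% c("CGI_promoter_active",
                                        "nonCGI_promoter_active",
                                        "promoter_poised")]
  expect_true(all(prom$class == "CGI_promoter_active"))
  expect_true(all(overlaps_any(prom, g$annotation$cgi)))
})

test_that("chromosomes too short for the element layout fail loudly", {
  expect_error(generate_genome(synthetic_config(n_chroms = 1L,
                                                chrom_length = 5e4,
                                                n_genes = 10L)),
               "too short")
})

test_that("coverage enrichment matches the planted occupancy", {
  cfg <- small_cfg()
  g <- generate_genome(cfg)

  # enrichment_fold = 1: inside/outside means agree within 5% (the
  # bound holds at >= 1e4 occupied micro-bins, so this world plants
  # ~2e5 bp of occupied elements)
  cfg1 <- small_cfg(enrichment_fold = 1, n_chroms = 3L,
                    chrom_length = 1e6, n_genes = 80L, n_dels = 400L)
  g1 <- generate_genome(cfg1)
  tr <- simulate_coverage(g1$annotation, g1$truth, "H3K18la", "tissue1",
                          cfg1)
  occ0 <- g1$truth$occupancy[mark == "H3K18la" & tissue == "tissue1" &
                               occupied == 1L]
  els <- merge_intervals(
    g1$truth$elements[element_id %in% occ0$element_id,
                      .(chrom, start, end)])
  expect_gte(sum(els$end - els$start) / cfg1$micro_bin, 1e4)
  qm_in <- quantify(list(x = tr), els)
  inside_bp <- sum(els$end - els$start)
  mean_in <- sum(qm_in$counts) / inside_bp
  genome_bp <- sum(g1$annotation$chrom_sizes)
  mean_out <- (track_total(tr) - sum(qm_in$counts)) /
    (genome_bp - inside_bp)
  expect_lt(abs(mean_in / mean_out - 1), 0.05)

  # owner tissue carries ~enrichment_fold times the other tissue's signal
  # over its specific enhancers
  spec <- g$truth$elements[class == "dELS_tissue_specific" &
                             owner_tissue == "tissue1"]
  occ1 <- g$truth$occupancy[mark == "H3K18la" & tissue == "tissue1" &
                              occupied == 1L]
  spec <- spec[element_id %in% occ1$element_id]
  ta <- simulate_coverage(g$annotation, g$truth, "H3K18la", "tissue1", cfg)
  tb <- simulate_coverage(g$annotation, g$truth, "H3K18la", "tissue2", cfg)
  qa <- quantify(list(x = ta), spec[, .(chrom, start, end)])
  qb <- quantify(list(x = tb), spec[, .(chrom, start, end)])
  ratio <- sum(qa$counts) / sum(qb$counts)
  expect_gt(ratio, cfg$enrichment_fold * 0.7)
  expect_lt(ratio, cfg$enrichment_fold * 1.3)

  # background_rate -> 0 confines signal to planted elements
  cfg0 <- small_cfg(background_rate = 1e-9)
  tr0 <- simulate_coverage(g$annotation, g$truth, "H3K18la", "tissue1", cfg0)
  occupied <- merge_intervals(
    g$truth$elements[element_id %in% occ1$element_id, .(chrom, start, end)])
  outside <- track_total(tr0) -
    sum(quantify(list(x = tr0), occupied)$counts)
  expect_equal(outside, 0)

  expect_error(simulate_coverage(g$annotation, g$truth, "H3K9me3",
                                 "tissue1", cfg), "unknown mark")
  expect_error(simulate_coverage(g$annotation, g$truth, "H3K18la",
                                 "liver", cfg), "unknown tissue")
})

test_that("occupancy marginals calibrate to the configured probability", {
  cfg <- synthetic_config(n_chroms = 3L, chrom_length = 1e6, n_genes = 30L,
                          n_dels = 300L, frac_dels_tissue_specific = 0,
                          seed = 5L)
  g <- generate_genome(cfg)
  shared <- g$truth$elements[class == "dELS_shared"]
  occ <- g$truth$occupancy[mark == "H3K18la" & tissue == "tissue1" &
                             element_id %in% shared$element_id]
  p <- cfg$occupancy[mark == "H3K18la" &
                       element_class == "dELS_shared"]$prob
  n <- nrow(occ)
  phat <- mean(occ$occupied)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("expression follows the planted monotone link", {
  cfg <- small_cfg(expression_noise_sd = 0)
  g <- generate_genome(cfg)
  ex <- simulate_expression(g$annotation, g$truth, "tissue1", cfg)
  tg <- g$truth$genes[tissue == "tissue1"]
  tg <- tg[match(ex$gene_id, gene_id)]
  expect_equal(cor(tg$intensity, ex$count, method = "spearman"), 1)

  # slope = 0: correlation within the 2/sqrt(n) null band
  cfg0 <- small_cfg(expr_slope = 0, n_genes = 100L, n_chroms = 3L,
                    chrom_length = 2e6)
  g0 <- generate_genome(cfg0)
  ex0 <- simulate_expression(g0$annotation, g0$truth, "tissue1", cfg0)
  tg0 <- g0$truth$genes[tissue == "tissue1"][match(ex0$gene_id, gene_id)]
  r0 <- suppressWarnings(cor(tg0$intensity, log2(ex0$count + 1),
                             method = "spearman"))
  expect_lt(abs(r0), 2 / sqrt(nrow(ex0)))
})
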