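fake_peaks <- function(chrom, start, end) {
  p <- data.table::data.table(chrom = chrom, start = start, end = end,
                              name = paste0("p", seq_along(start)),
                              auc = 1, max_value = 1,
                              summit = floor((start + end) / 2))
  data.table::setattr(p, "class", c("PeakSet", class(p)))
  p
}

test_that("marking table enumerates Venn cells exactly", {
  # elements P1, P2, P3; marks A covers {P1,P2}, B {P2}, C {P2,P3}
  el <- data.table::data.table(chrom = "c", start = c(0, 100, 200),
                               end = c(50, 150, 250),
                               element_id = c("P1", "P2", "P3"))
  pk <- list(A = fake_peaks(c("c", "c"), c(0, 100), c(50, 150)),
             B = fake_peaks("c", 100, 150),
             C = fake_peaks(c("c", "c"), c(100, 200), c(150, 250)))
  mt <- build_marking_table(el, pk)
  expect_equal(mt$cell, c("A", "A+B+C", "C"))
  vc <- venn_counts(mt)
  expect_equal(vc[cell == "A"]$N, 1L)
  expect_equal(vc[cell == "A+B+C"]$N, 1L)
  expect_equal(sum(vc[cell != "none"]$N), 3L)
  expect_equal(sum(vc[cell != "none"]$fraction), 1)

  # no peaks anywhere: all cells "none"
  none <- build_marking_table(el, list(A = fake_peaks("c", 900, 950)))
  expect_true(all(none$cell == "none"))
})

test_that("group assignment partitions actively marked elements", {
  el <- data.table::data.table(chrom = "c", start = (0:4) * 100,
                               end = (0:4) * 100 + 50,
                               element_id = paste0("e", 1:5))
  # e1: all three; e2: ac+me3; e3: me3 only; e4: la only; e5: none
  pk <- list(
    H3K18la = fake_peaks(c("c", "c"), c(0, 300), c(50, 350)),
    H3K27ac = fake_peaks(c("c", "c"), c(0, 100), c(50, 150)),
    H3K4me3 = fake_peaks(c("c", "c", "c"), c(0, 100, 200),
                         c(50, 150, 250)))
  g <- assign_groups(build_marking_table(el, pk))
  expect_equal(g[g$element_id == "e1"]$group, "group1")
  expect_equal(g[g$element_id == "e2"]$group, "group2")
  expect_equal(g[g$element_id == "e3"]$group, "group3")
  expect_equal(g[g$element_id == "e4"]$group, "H3K18la") # residual cell
  expect_false("e5" %in% g$element_id)
  expect_equal(nrow(g), 4L) # groups + residuals partition the active set
})

test_that("Mann-Whitney: exact enumeration case and tie handling", {
  # {1,2,3} vs {4,5,6}: the most extreme of the C(6,3)=20 rank splits,
  # two-sided doubles 1/20 to 0.1
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$p, 0.1)
  # identical constant samples: p = 1
  expect_equal(mann_whitney(rep(2, 5), rep(2, 5))$p, 1)
  # large-sample path runs the tie-corrected normal approximation
  x <- rep(1:20, 3); y <- rep(6:25, 3)
  expect_lt(mann_whitney(x, y)$p, 0.05)
})

test_that("expression_by_group orders planted group means", {
  set.seed(5)
  groups <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:60),
    element_id = sprintf("g%02d", 1:60),
    group = rep(c("group1", "group2", "group3"), each = 20))
  expr <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:60),
    log2rpkm = rnorm(60, rep(c(8, 6, 4), each = 20), 1))
  res <- expression_by_group(groups, expr)
  med <- res$stats$median[match(c("group1", "group2", "group3"),
                                res$stats$group)]
  expect_true(med[1] > med[2] && med[2] > med[3])
  p12 <- res$tests[group_a == "group1" & group_b == "group2"]$p
  expect_lt(p12, 0.05)
  expect_error(expression_by_group(groups[0], expr), "no genes")
})

test_that("correlate: monotone invariance, self-correlation, CI", {
  x <- sort(rnorm(50))
  expect_equal(correlate(x, exp(x), "spearman")$R, 1)
  self <- correlate(x, x, "pearson")
  expect_equal(self$R, 1)
  expect_lt(self$p, 1e-10)
  set.seed(13)
  n <- 2000; rho <- 0.5
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(correlate(z1, z2, "pearson")$R - rho), 0.05)
  expect_error(correlate(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("MDS embedding preserves distances where it can", {
  qm <- list(counts = cbind(a = c(rep(0, 50), rnorm(50)),
                            b = c(rep(0, 50), rnorm(50) + 2)),
             samples = c("a", "b"))
  m <- mds_embed(qm, top_features = 50)
  # two samples: the embedded 1-D distance equals the input distance
  expect_equal(unname(abs(m$coords[1, 1] - m$coords[2, 1])),
               m$dist["a", "b"], tolerance = 1e-9)

  # duplicated sample at distance 0 with identical coordinates
  qm3 <- list(counts = cbind(a = qm$counts[, 1], b = qm$counts[, 2],
                             a2 = qm$counts[, 1]),
              samples = c("a", "b", "a2"))
  m3 <- mds_embed(qm3, top_features = 50)
  expect_equal(m3$dist["a", "a2"], 0)
  expect_equal(m3$coords["a", ], m3$coords["a2", ], tolerance = 1e-6)

  # three mutually Euclidean-realizable distances embed exactly
  # (double-centering oracle: points on a line)
  qm_line <- list(counts = cbind(a = rep(0, 100), b = rep(1, 100),
                                 c = rep(3, 100)),
                  samples = c("a", "b", "c"))
  ml <- mds_embed(qm_line, top_features = 100)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sqrt(sum((ml$coords[i, ] - ml$coords[j, ])^2)),
                 ml$dist[i, j], tolerance = 1e-6)
  }
  expect_error(mds_embed(list(counts = matrix(1, 5, 1), samples = "a")),
               "2 samples")
})

test_that("dELS linkage matches the brute-force oracle", {
  ann <- structure(list(genes = data.table::data.table(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    tss = c(5000, 20000), gene_start = c(5000, 20000),
    gene_end = c(8000, 23000), length = 3000,
    biotype = "protein_coding", housekeeping = FALSE),
    cgi = NULL, exons = NULL, chrom_sizes = c(chr1 = 50000),
    elements = NULL), class = "GenomeAnnotation")
  # nearest promoter wins
  l <- link_dels_to_genes(iv("chr1", 10000, 10500), ann)
  expect_equal(l$gene_id, "g1")
  expect_equal(l$distance, 10000 - 7000) # promoter g1 ends at 7000
  # overlapping nearest promoter is excluded; next one linked
  l2 <- link_dels_to_genes(iv("chr1", 6900, 7400), ann)
  expect_equal(l2$gene_id, "g2")
  # exact tie: smaller promoter start, then smaller id
  ann$genes$tss <- c(5000, 25000)
  mid <- iv("chr1", 13000, 17000) # gaps: 13000-7000=6000; 23000-17000=6000
  lt <- link_dels_to_genes(mid, ann)
  expect_equal(lt$gene_id, "g1")

  # 100 random toy configurations against the O(n*m) oracle
  set.seed(99)
  for (i in 1:20) {
    ng <- sample(2:6, 1)
    genes <- data.table::data.table(
      gene_id = sprintf("g%02d", 1:ng),
      chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
      strand = "+",
      tss = sample(seq(3000, 95000, 500), ng),
      biotype = "protein_coding", housekeeping = FALSE)
    genes[, `:=`(gene_start = tss, gene_end = tss + 1000, length = 1000)]
    ann_i <- structure(list(genes = genes, cgi = NULL, exons = NULL,
                            chrom_sizes = c(chr1 = 100000, chr2 = 100000),
                            elements = NULL), class = "GenomeAnnotation")
    nd <- 5
    ds <- sample(seq(0, 99000, 250), nd)
    dels <- iv(sample(c("chr1", "chr2"), nd, replace = TRUE), ds, ds + 400)
    got <- link_dels_to_genes(dels, ann_i)
    want <- oracle_link(dels, genes)
    expect_equal(got$gene_id, want$gene_id)
    expect_equal(got$distance, want$distance)
  }
})

test_that("top-ranked dELS ordering and deduplication", {
  ann <- structure(list(genes = data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 1000,
    gene_start = 1000, gene_end = 2000, length = 1000,
    biotype = "protein_coding", housekeeping = FALSE),
    cgi = NULL, exons = NULL, chrom_sizes = c(chr1 = 100000),
    elements = NULL), class = "GenomeAnnotation")
  regions <- iv(rep("chr1", 3), c(10000, 20000, 30000),
                c(10400, 20400, 30400))
  qm <- list(regions = regions,
             counts = matrix(c(5, 9, 1), 3, 1,
                             dimnames = list(NULL, "s")),
             samples = "s")
  top1 <- top_ranked_dels(qm, ann, n = 1)
  expect_equal(top1$start, 20000) # highest signal first
  # equal signals: deterministic coordinate order, one gene kept once
  qm$counts <- matrix(c(2, 2, 2), 3, 1)
  expect_warning(all_links <- top_ranked_dels(qm, ann, n = 5), "only 3")
  expect_equal(nrow(all_links), 1L) # all link to g1; deduplicated
  expect_equal(all_links$start, 10000) # best (first-coordinate) rank kept
})

test_that("CGI-restricted correlation beats all-promoter correlation when
           noise is planted only at non-CGI promoters", {
  set.seed(404)
  n <- 200
  is_cgi <- rep(c(TRUE, FALSE), each = n / 2)
  intensity <- runif(n, 0, 2)
  expr <- 3 + 2 * intensity + rnorm(n, 0, 0.5)
  expr[!is_cgi] <- expr[!is_cgi] + rnorm(sum(!is_cgi), 0, 3) # planted noise
  r_all <- correlate(intensity, expr, "spearman")$R
  r_cgi <- correlate(intensity[is_cgi], expr[is_cgi], "spearman")$R
  expect_gte(r_cgi, r_all)
})

test_that("MDS places replicate pairs closer than other samples", {
  cfg <- synthetic_config(n_chroms = 2L, chrom_length = 4e5, n_genes = 16L,
                          n_dels = 24L, n_tissues = 2L,
                          marks = c("H3K18la", "H3K27me3"), seed = 7L,
                          occupancy = default_occupancy())
  g <- generate_genome(cfg)
  tracks <- list()
  for (ts in cfg$tissues) for (mk in cfg$marks) for (r in 1:2)
    tracks[[sprintf("%s_%s_rep%d", ts, mk, r)]] <-
      simulate_coverage(g$annotation, g$truth, mk, ts, cfg, r)
  tiles <- tile_genome(g$annotation$chrom_sizes, 3000)
  qm <- normalize_quant(quantify(tracks, tiles), "log2CPM")
  m <- mds_embed(qm, top_features = 100)
  d <- m$dist
  for (ts in cfg$tissues) for (mk in cfg$marks) {
    a <- sprintf("%s_%s_rep1", ts, mk); b <- sprintf("%s_%s_rep2", ts, mk)
    others <- setdiff(rownames(d), c(a, b))
    # silhouette-positive: within-pair distance below every cross distance
    expect_lt(d[a, b], min(d[a, others]))
    expect_lt(d[a, b], min(d[b, others]))
  }
})
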