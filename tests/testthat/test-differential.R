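raw_qm <- function(counts, lib = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  q <- list(regions = iv(rep("chr1", n), (seq_len(n) - 1) * 1000,
                         seq_len(n) * 1000),
            counts = counts,
            samples = colnames(counts) %||% paste0("s", seq_len(ncol(counts))),
            normalization = "raw",
            lib_sizes = lib %||% pmax(colSums(counts), 1),
            lengths = rep(1000, n))
  class(q) <- "QuantMatrix"
  q
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical conditions give log2FC 0 and p 1", {
  set.seed(2)
  m <- matrix(rpois(200, 20), 100, 2)
  d <- differential_regions(raw_qm(m), raw_qm(m))
  expect_true(all(d$log2fc == 0))
  expect_true(all(d$p == 1))
  expect_true(all(d$fdr == 1))
  expect_false(any(d$significant))
})

test_that("condition swap negates log2FC and preserves p", {
  set.seed(3)
  a <- matrix(rpois(400, 30), 200, 2)
  b <- matrix(rpois(400, 45), 200, 2)
  d1 <- differential_regions(raw_qm(a), raw_qm(b))
  d2 <- differential_regions(raw_qm(b), raw_qm(a))
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up", {
  set.seed(4)
  p <- runif(500)^2
  expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  # FDR >= p always after BH, and the DiffTable carries that through
  a <- matrix(rpois(100, 10), 50, 2); b <- matrix(rpois(100, 14), 50, 2)
  d <- differential_regions(raw_qm(a), raw_qm(b))
  expect_true(all(d$fdr >= d$p - 1e-12))
  expect_true(all(d$fdr <= 1))
  expect_equal(d$fdr, bh_stepup(d$p), tolerance = 1e-12)
})

test_that("planted 4-fold regions are recovered", {
  # 2000 regions, NB noise, 100 planted at 4x in condition A. With CPM
  # normalization the planted regions inflate A's library by a factor
  # 2300/2000, so the expected estimated log2FC is
  # log2(4) - log2(1.15) = 1.795, not 2 (analytic oracle).
  set.seed(6)
  n <- 2000; idx <- 1:100
  mu <- rep(100, n); mu_a <- mu; mu_a[idx] <- 400
  draw <- function(mu) matrix(rnbinom(n * 2, mu = mu, size = 25), n, 2)
  a <- draw(mu_a); b <- draw(mu)
  d <- differential_regions(raw_qm(a), raw_qm(b))
  expected_lfc <- log2(4) - log2(sum(mu_a) / sum(mu))
  expect_lt(abs(mean(d$log2fc[idx]) - expected_lfc), 0.1)
  expect_gte(mean(d$significant[idx]), 0.9)
  # specificity: few unplanted regions flagged
  expect_lte(mean(d$significant[-idx]), 0.02)
})

test_that("region set mismatch and non-raw input are rejected", {
  a <- raw_qm(matrix(rpois(20, 5), 10, 2))
  b <- raw_qm(matrix(rpois(18, 5), 9, 2))
  expect_error(differential_regions(a, b), "region sets differ")
  an <- normalize_quant(a, "CPM")
  expect_error(differential_regions(an, an), "raw")
})

test_that("change-change correlation filters then correlates", {
  set.seed(8)
  n <- 60
  dm <- data.table::data.table(
    chrom = "chr1", start = (1:n) * 100, end = (1:n) * 100 + 50,
    mean_a = 1, mean_b = 1,
    log2fc = c(rnorm(n / 2, 2, 0.3), rnorm(n / 2, 0, 0.05)),
    p = c(rep(1e-6, n / 2), rep(0.9, n / 2)))
  dm[, fdr := stats::p.adjust(p, "BH")]
  dm[, significant := fdr < 0.05 & abs(log2fc) > 0.5]
  data.table::setattr(dm, "class", c("DiffTable", class(dm)))
  de <- data.table::data.table(gene_id = sprintf("g%03d", 1:n),
                               log2fc = dm$log2fc, p = dm$p,
                               fdr = dm$fdr)
  links <- data.table::data.table(region_idx = 1:n,
                                  gene_id = sprintf("g%03d", 1:n))
  res <- diff_change_correlation(dm, de, links)
  expect_equal(res$R, 1, tolerance = 1e-12)
  # entries failing the filters never reach the scatter table
  expect_true(all(res$table$fdr < 0.05))
  expect_true(all(abs(res$table$log2fc) > 0.5))
  expect_true(all(abs(res$table$expr_log2fc) > 0.5))
  expect_equal(res$n, n / 2)

  # planted coupling: expr lfc = 0.8 * mark lfc + noise(sd 0.5);
  # population R = 0.8*sigma/sqrt(0.64*sigma^2 + 0.25)
  set.seed(9)
  n2 <- 500; sigma <- 1.5
  mfc <- rnorm(n2, 0, sigma)
  efc <- 0.8 * mfc + rnorm(n2, 0, 0.5)
  keep <- abs(mfc) > 0.5 & abs(efc) > 0.5
  r_pop <- 0.8 * sigma / sqrt(0.64 * sigma^2 + 0.25)
  r_obs <- cor(mfc[keep], efc[keep])
  expect_lt(abs(r_obs - r_pop), 0.1)
})

test_that("fold changes grouped by element class detect planted shifts", {
  set.seed(10)
  n <- 300
  classes <- rep(c("dELS", "promoter", "other"), each = n / 3)
  lfc <- c(rnorm(n / 3, 0, 1.5), rnorm(n / 3, 0, 0.3), rnorm(n / 3, 0, 0.3))
  d <- data.table::data.table(chrom = "c", start = 1:n, end = (1:n) + 1,
                              mean_a = 1, mean_b = 1, log2fc = lfc,
                              p = 0.5, fdr = 0.5, significant = FALSE)
  data.table::setattr(d, "class", c("DiffTable", class(d)))
  res <- fc_by_elementclass(d, classes)
  p_dp <- res$tests[class_a == "dELS" & class_b == "promoter"]$p
  expect_lt(p_dp, 0.05)
  med <- res$stats$median_abs_lfc
  expect_gt(med[res$stats$class == "dELS"],
            med[res$stats$class == "promoter"])
  # single class: distribution only, no tests
  one <- fc_by_elementclass(d, rep("x", n))
  expect_null(one$tests)
  expect_equal(one$stats$n, n)
})

test_that("expression shifts by promoter-peak class use the thresholds", {
  # 10-gene toy with hand-set p and FC: hand count of the pass list
  d <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:10),
    mean_a = 1, mean_b = 1,
    log2fc = c(1.2, 0.4, -0.8, 0.6, 0.1, -2, 0.55, 0.7, -0.45, 3),
    p = c(0.001, 0.001, 0.5, 0.009, 0.2, 0.004, 0.011, 0.009, 0.001, 0.02))
  d[, fdr := stats::p.adjust(p, "BH")]
  data.table::setattr(d, "class", c("DiffTable", class(d)))
  cls <- stats::setNames(rep(c("mt", "none"), 5), d$gene_id)
  res <- expression_shift_by_peakclass(d, cls)
  # pass requires p < 0.01 AND |lfc| > 0.5: g01, g04, g06, g08
  expect_setequal(res$significant$gene_id, c("g01", "g04", "g06", "g08"))
  expect_equal(nrow(res$stats), 2L)

  # planted +0.75 shift for the "mt" class is detected
  set.seed(11)
  d2 <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:200),
    mean_a = 1, mean_b = 1,
    log2fc = c(rnorm(100, 0.75, 0.5), rnorm(100, 0, 0.5)),
    p = 0.5, fdr = 0.5)
  data.table::setattr(d2, "class", c("DiffTable", class(d2)))
  cls2 <- stats::setNames(rep(c("mt", "none"), each = 100), d2$gene_id)
  res2 <- expression_shift_by_peakclass(d2, cls2)
  expect_lt(res2$tests$p[1], 0.05)
  expect_gt(res2$stats[class == "mt"]$median_lfc,
            res2$stats[class == "none"]$median_lfc)
})
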