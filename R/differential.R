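## Pairwise differential marking / expression ---------------------------------
##
## A negative-binomial exact test conditioned on the per-region total
## count, with one common dispersion estimated by the method of moments
## across regions (Poisson fallback when the moment estimate is not
## positive). Counts are first scaled to a common library size so the
## conditional argument applies; log2 fold changes are computed on CPM
## means with a 0.5 pseudocount, which makes them finite and exactly
## antisymmetric under condition swap.

## moment estimate of the common NB dispersion phi (var = mu + phi mu^2)
## from library-size-adjusted counts; uses within-condition variability
## when both conditions have >= 2 replicates, otherwise pools all
## samples (logged limitation: with single replicates the estimate
## absorbs the condition effect).
estimate_dispersion <- function(ya, yb) {
  na <- ncol(ya); nb <- ncol(yb)
  if (na >= 2L && nb >= 2L) {
    ma <- rowMeans(ya); mb <- rowMeans(yb)
    va <- apply(ya, 1, var); vb <- apply(yb, 1, var)
    num <- sum((va - ma) * (na - 1) + (vb - mb) * (nb - 1))
    den <- sum(ma^2 * (na - 1) + mb^2 * (nb - 1))
  } else {
    y <- cbind(ya, yb)
    m <- rowMeans(y); v <- apply(y, 1, var)
    num <- sum(v - m); den <- sum(m^2)
  }
  if (den <= 0) return(0)
  max(num / den, 0)
}

## two-sided exact test for sa vs sb (summed adjusted counts over na/nb
## replicates), conditional on s = sa + sb. NB with common dispersion
## phi; phi = 0 reduces to the conditional binomial (Poisson) test.
## p = sum of conditional probabilities not exceeding that of the
## observed split.
exact_count_test <- function(sa, sb, na, nb, phi) {
  s <- sa + sb
  if (s == 0) return(1)
  k <- 0:s
  if (phi > 0) {
    mu <- s / (na + nb)
    lpa <- dnbinom(k, size = na / phi, mu = na * mu, log = TRUE)
    lpb <- dnbinom(s - k, size = nb / phi, mu = nb * mu, log = TRUE)
    lp <- lpa + lpb
    lp <- lp - max(lp)
    pr <- exp(lp); pr <- pr / sum(pr)
  } else {
    pr <- dbinom(k, s, na / (na + nb))
  }
  obs <- pr[sa + 1]
  sel <- pr <= obs * (1 + 1e-10)
  if (all(sel)) return(1) # observed split is modal: nothing more extreme
  min(1, sum(pr[sel]))
}

#' Differential marking between two conditions over a shared region set
#'
#' @param quant_a,quant_b raw `QuantMatrix` objects over the identical
#'   region set (one column per replicate)
#' @param fdr,min_lfc significance thresholds for the `significant`
#'   flag (defaults FDR < 0.05, |log2FC| > 0.5)
#' @param pseudocount added to the CPM means before the log2 ratio
#' @return data.table of class `DiffTable`: region coordinates, mean
#'   CPM per condition, log2fc (A over B), p, fdr, significant
#' @export
differential_regions <- function(quant_a, quant_b, fdr = 0.05,
                                 min_lfc = 0.5, pseudocount = 0.5) {
  assert_that(identical(quant_a$regions$chrom, quant_b$regions$chrom) &&
                identical(quant_a$regions$start, quant_b$regions$start) &&
                identical(quant_a$regions$end, quant_b$regions$end),
              "region sets differ between conditions")
  assert_that(quant_a$normalization == "raw" &&
                quant_b$normalization == "raw",
              "differential testing needs raw counts")
  na <- ncol(quant_a$counts); nb <- ncol(quant_b$counts)
  cpm_a <- sweep(quant_a$counts, 2, quant_a$lib_sizes, "/") * 1e6
  cpm_b <- sweep(quant_b$counts, 2, quant_b$lib_sizes, "/") * 1e6
  mean_a <- rowMeans(cpm_a); mean_b <- rowMeans(cpm_b)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  ## adjust raw counts to the grand mean library size, then round: the
  ## exact test conditions on the total of equal-library counts
  ref <- exp(mean(log(c(quant_a$lib_sizes, quant_b$lib_sizes))))
  ya <- round(sweep(quant_a$counts, 2, quant_a$lib_sizes, "/") * ref)
  yb <- round(sweep(quant_b$counts, 2, quant_b$lib_sizes, "/") * ref)
  phi <- estimate_dispersion(ya, yb)
  sa <- rowSums(ya); sb <- rowSums(yb)
  p <- vapply(seq_along(sa), function(i)
    exact_count_test(sa[i], sb[i], na, nb, phi), 0)
  fdr_v <- p.adjust(p, method = "BH")
  out <- data.table(chrom = quant_a$regions$chrom,
                    start = quant_a$regions$start,
                    end = quant_a$regions$end,
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2fc, p = p, fdr = fdr_v,
                    significant = fdr_v < fdr & abs(log2fc) > min_lfc)
  setattr(out, "class", c("DiffTable", class(out)))
  setattr(out, "dispersion", phi)
  setattr(out, "thresholds", c(fdr = fdr, min_lfc = min_lfc))
  out[]
}

#' Differential expression between two count tables (gene level)
#'
#' Same machinery as [differential_regions()] on gene count matrices.
#'
#' @param counts_a,counts_b matrices genes x replicates over identical
#'   genes (rownames = gene ids)
#' @param fdr,min_lfc thresholds for the `significant` flag
#' @return `DiffTable` keyed by gene_id
#' @export
differential_expression <- function(counts_a, counts_b, fdr = 0.05,
                                    min_lfc = 0.5) {
  counts_a <- as.matrix(counts_a); counts_b <- as.matrix(counts_b)
  assert_that(nrow(counts_a) == nrow(counts_b),
              "gene sets differ between conditions")
  ids <- rownames(counts_a) %||% sprintf("gene%05d", seq_len(nrow(counts_a)))
  qa <- list(regions = data.table(chrom = "genes",
                                  start = seq_len(nrow(counts_a)) - 1,
                                  end = seq_len(nrow(counts_a))),
             counts = counts_a, normalization = "raw",
             lib_sizes = pmax(colSums(counts_a), 1),
             samples = colnames(counts_a))
  qb <- qa; qb$counts <- counts_b; qb$lib_sizes <- pmax(colSums(counts_b), 1)
  qb$samples <- colnames(counts_b)
  out <- differential_regions(qa, qb, fdr = fdr, min_lfc = min_lfc)
  out[, `:=`(gene_id = ids, chrom = NULL, start = NULL, end = NULL)]
  setcolorder(out, "gene_id")
  out[]
}

#' Correlation between differential marking and differential expression
#'
#' Marks-side entries must pass FDR and |log2FC| thresholds; the
#' expression side is filtered on |log2FC| only (its FDR filter is
#' optional). Matched pairs come from a region -> gene map (promoter
#' ownership or nearest-gene dELS links); Pearson correlation on the
#' paired log2 fold changes.
#'
#' @param diff_marks `DiffTable` over regions
#' @param diff_expr `DiffTable` with `gene_id`
#' @param links data.table mapping region row -> gene: columns
#'   `region_idx`, `gene_id`
#' @param fdr,min_lfc thresholds (marks side)
#' @param expr_min_lfc expression |log2FC| threshold
#' @param expr_fdr optional expression FDR threshold (NULL = none)
#' @return list(R, p, n, table)
#' @export
diff_change_correlation <- function(diff_marks, diff_expr, links,
                                    fdr = 0.05, min_lfc = 0.5,
                                    expr_min_lfc = 0.5, expr_fdr = NULL) {
  keep_m <- which(diff_marks$fdr < fdr & abs(diff_marks$log2fc) > min_lfc)
  em <- diff_expr[abs(log2fc) > expr_min_lfc]
  if (!is.null(expr_fdr)) em <- em[fdr < expr_fdr]
  tab <- merge(links[region_idx %in% keep_m],
               diff_marks[keep_m][, region_idx := keep_m],
               by = "region_idx")
  tab <- merge(tab, em[, .(gene_id, expr_log2fc = log2fc)], by = "gene_id")
  assert_that(nrow(tab) >= 3L,
              "fewer than 3 matched pairs pass the filters")
  ct <- correlate(tab$log2fc, tab$expr_log2fc, "pearson")
  list(R = ct$R, p = ct$p, n = nrow(tab), table = tab)
}

#' Fold-change distributions by element class, with pairwise tests
#'
#' @param diff `DiffTable` over regions
#' @param classes character vector, one label per region (unlabeled
#'   regions should carry "other")
#' @param strict_fdr,strict_lfc thresholds defining the "strongly
#'   significant" regions counted per class (defaults FDR < 0.05,
#'   |log2FC| > 1.5)
#' @return list: `stats` per class (n, median |log2FC|, strong count),
#'   `tests` pairwise two-sided Mann-Whitney on |log2FC| (NULL with a
#'   single class)
#' @export
fc_by_elementclass <- function(diff, classes, strict_fdr = 0.05,
                               strict_lfc = 1.5) {
  assert_that(length(classes) == nrow(diff),
              "need one class label per region")
  dt <- data.table(class = classes, abs_lfc = abs(diff$log2fc),
                   strong = diff$fdr < strict_fdr &
                     abs(diff$log2fc) > strict_lfc)
  stats <- dt[, .(n = .N, median_abs_lfc = median(abs_lfc),
                  n_strong = sum(strong)), by = class][order(class)]
  cl <- sort(unique(dt$class))
  tests <- NULL
  if (length(cl) >= 2L) {
    tests <- list()
    for (i in seq_len(length(cl) - 1L)) for (j in (i + 1L):length(cl)) {
      mw <- mann_whitney(dt[class == cl[i]]$abs_lfc,
                         dt[class == cl[j]]$abs_lfc)
      tests[[length(tests) + 1L]] <-
        data.table(class_a = cl[i], class_b = cl[j], U = mw$U, p = mw$p)
    }
    tests <- rbindlist(tests)
  }
  list(stats = stats, tests = tests)
}

#' Expression shifts grouped by promoter-peak presence class
#'
#' Genes are classed by where their promoter carries a peak ("a", "b",
#' "both", "none" for two conditions); per-class distributions of a
#' treatment's expression log2FC are compared pairwise, and genes
#' passing the nominal significance thresholds (default P < 0.01 and
#' |log2FC| > 0.5) are listed with their class.
#'
#' @param diff_expr `DiffTable` with `gene_id`
#' @param peak_class named character vector gene_id -> class
#' @param p_nominal,min_lfc thresholds for the significant-gene list
#' @return list: `stats` per class, `tests` pairwise Mann-Whitney,
#'   `significant` gene table
#' @export
expression_shift_by_peakclass <- function(diff_expr, peak_class,
                                          p_nominal = 0.01,
                                          min_lfc = 0.5) {
  dt <- copy(diff_expr)
  dt[, class := peak_class[gene_id]]
  dt[is.na(class), class := "none"]
  stats <- dt[, .(n = .N, median_lfc = median(log2fc),
                  mean_lfc = mean(log2fc)), by = class][order(class)]
  cl <- sort(unique(dt$class))
  tests <- NULL
  if (length(cl) >= 2L) {
    tests <- list()
    for (i in seq_len(length(cl) - 1L)) for (j in (i + 1L):length(cl)) {
      mw <- mann_whitney(dt[class == cl[i]]$log2fc,
                         dt[class == cl[j]]$log2fc)
      tests[[length(tests) + 1L]] <-
        data.table(class_a = cl[i], class_b = cl[j], U = mw$U, p = mw$p)
    }
    tests <- rbindlist(tests)
  }
  sig <- dt[p < p_nominal & abs(log2fc) > min_lfc,
            .(gene_id, log2fc, p, fdr, class)]
  list(stats = stats, tests = tests, significant = sig)
}

#' Brute-force Benjamini-Hochberg step-up (verification oracle)
#'
#' Direct implementation of the step-up procedure, kept independent of
#' `stats::p.adjust` so tests can cross-check the two.
#'
#' @param p vector of p-values
#' @return adjusted values
#' @export
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}
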