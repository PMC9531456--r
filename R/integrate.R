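## Marking combinatorics, expression integration, clustering, linkage --------

#' Boolean element-by-mark marking table
#'
#' An element carries a mark iff it intersects a peak of that mark by at
#' least 1 bp. Rows are elements (promoters or enhancer-like elements),
#' columns the marks; the Venn cell of an element is the set of marks it
#' carries.
#'
#' @param elements interval table with an `element_id` column (created
#'   if absent); may carry `class` and `gene_id`
#' @param peaksets named list mark -> `PeakSet`
#' @return data.table of class `MarkingTable`: element columns plus one
#'   logical column per mark and a `cell` label ("A+B", "none", ...)
#' @export
build_marking_table <- function(elements, peaksets) {
  el <- as.data.table(elements)
  if (!"element_id" %in% names(el))
    el[, element_id := sprintf("el%04d", .I)]
  assert_that(length(peaksets) >= 1L && !is.null(names(peaksets)),
              "need a named list of peak sets")
  out <- copy(el)
  for (mk in names(peaksets)) {
    set(out, j = mk,
        value = overlaps_any(el[, .(chrom, start, end)], peaksets[[mk]]))
  }
  marks <- names(peaksets)
  cell <- apply(as.matrix(out[, marks, with = FALSE]), 1, function(r) {
    on <- marks[r]
    if (length(on) == 0L) "none" else paste(on, collapse = "+")
  })
  set(out, j = "cell", value = cell)
  setattr(out, "class", c("MarkingTable", class(out)))
  setattr(out, "marks", marks)
  out[]
}

#' Venn cell counts and fractions of actively marked elements
#' @param marking a [build_marking_table()] result
#' @return data.table: cell, count, fraction (of elements carrying at
#'   least one mark)
#' @export
venn_counts <- function(marking) {
  tab <- marking[, .N, by = cell]
  active <- sum(tab[cell != "none"]$N)
  tab[, fraction := ifelse(cell == "none", NA_real_, N / active)]
  setorder(tab, -N)
  tab[]
}

#' Assign active-promoter marking groups
#'
#' The three headline combinations of active marks: group1 = all three
#' (lactylation + acetylation + trimethylation), group2 = H3K27ac +
#' H3K4me3 without the lactylation mark, group3 = H3K4me3 only.
#' Elements in other non-empty Venn cells keep their cell label, so the
#' groups plus residual cells partition the actively marked elements.
#'
#' @param marking a [build_marking_table()] result
#' @param mark_la,mark_ac,mark_me3 column names of the three active marks
#' @return data.table: element_id, gene_id (when present), group
#' @export
assign_groups <- function(marking, mark_la = "H3K18la",
                          mark_ac = "H3K27ac", mark_me3 = "H3K4me3") {
  for (m in c(mark_la, mark_ac, mark_me3))
    assert_that(m %in% names(marking), "mark '%s' missing from table", m)
  la <- marking[[mark_la]]; ac <- marking[[mark_ac]]
  me <- marking[[mark_me3]]
  group <- rep(NA_character_, nrow(marking))
  group[la & ac & me] <- "group1"
  group[!la & ac & me] <- "group2"
  group[!la & !ac & me] <- "group3"
  other <- is.na(group) & marking$cell != "none"
  group[other] <- marking$cell[other]
  out <- data.table(element_id = marking$element_id, group = group)
  if ("gene_id" %in% names(marking)) out[, gene_id := marking$gene_id]
  out[!is.na(group)][]
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when the combined sample size is below 24 and there are no
#' ties; otherwise the normal approximation with tie correction (and
#' continuity correction).
#'
#' @param x,y numeric vectors
#' @return list(U, p)
#' @export
mann_whitney <- function(x, y) {
  assert_that(length(x) >= 1L && length(y) >= 1L, "empty group")
  if (length(unique(c(x, y))) == 1L) return(list(U = length(x) * length(y) / 2,
                                                 p = 1))
  exact <- (length(x) + length(y)) < 24 && !anyDuplicated(c(x, y))
  w <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                    alternative = "two.sided"))
  list(U = unname(w$statistic), p = w$p.value)
}

#' Per-group expression distributions with pairwise Mann-Whitney tests
#'
#' @param groups a [assign_groups()]-style table with `gene_id` and
#'   `group`
#' @param expr expression values per gene: data.table with `gene_id` and
#'   a value column (e.g. log2RPKM)
#' @param value name of the value column
#' @return list: `stats` (per-group n/median/mean), `tests` (pairwise
#'   two-sided Mann-Whitney p-values), `values` (per-gene long table)
#' @export
expression_by_group <- function(groups, expr, value = "log2rpkm") {
  assert_that(value %in% names(expr), "value column '%s' missing", value)
  m <- merge(groups, expr[, c("gene_id", value), with = FALSE],
             by = "gene_id")
  setnames(m, value, "value")
  m <- m[!is.na(group) & !is.na(value)]
  assert_that(nrow(m) > 0L, "no genes matched to groups")
  gsizes <- m[, .N, by = group]
  assert_that(all(gsizes$N > 0L), "empty group")
  stats <- m[, .(n = .N, median = median(value), mean = mean(value)),
             by = group][order(group)]
  gl <- sort(unique(m$group))
  tests <- list()
  if (length(gl) >= 2L) {
    for (i in seq_len(length(gl) - 1L)) for (j in (i + 1L):length(gl)) {
      mw <- mann_whitney(m[group == gl[i]]$value, m[group == gl[j]]$value)
      tests[[length(tests) + 1L]] <-
        data.table(group_a = gl[i], group_b = gl[j], U = mw$U, p = mw$p)
    }
  }
  list(stats = stats,
       tests = if (length(tests)) rbindlist(tests) else data.table(),
       values = m)
}

#' Correlation with two-sided p-value
#'
#' Pearson for mark-vs-mark comparisons, Spearman for mark-vs-expression
#' (rank-based, robust to the monotone but non-linear link).
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param method "pearson" or "spearman"
#' @return list(R, p, n)
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_that(length(x) == length(y), "length mismatch")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 3L, "need at least 3 paired observations")
  assert_that(sd(x) > 0 && sd(y) > 0, "zero variance input")
  ct <- suppressWarnings(cor.test(x, y, method = method,
                                  alternative = "two.sided"))
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Classical MDS embedding of samples from a log-scale QuantMatrix
#'
#' The pairwise distance between two samples is the root-mean-square of
#' their `top_features` largest absolute log2 differences (computed per
#' pair - the "leading fold-change" style distance used for epigenome
#' sample clustering), embedded by Torgerson double-centering. The sign
#' of each axis is fixed so the first sample has non-negative
#' coordinates.
#'
#' @param qm a `QuantMatrix` on a log2 scale (or any matrix-like with
#'   `counts` and `samples`)
#' @param top_features number of features entering each pairwise distance
#' @param k embedding dimension (default 2)
#' @return list: `coords` (samples x k), `dist` (sample distance matrix)
#' @export
mds_embed <- function(qm, top_features = 500, k = 2) {
  x <- qm$counts
  n <- ncol(x)
  assert_that(n >= 2L, "need at least 2 samples")
  d <- matrix(0, n, n, dimnames = list(qm$samples, qm$samples))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dif <- abs(x[, i] - x[, j])
    top <- sort(dif, decreasing = TRUE)[seq_len(min(top_features,
                                                    length(dif)))]
    d[i, j] <- d[j, i] <- sqrt(mean(top^2))
  }
  k_eff <- min(k, n - 1L)
  co <- suppressWarnings(cmdscale(stats::as.dist(d), k = k_eff))
  if (is.null(dim(co))) co <- matrix(co, ncol = 1)
  if (ncol(co) < k) co <- cbind(co, matrix(0, n, k - ncol(co)))
  for (ax in seq_len(ncol(co)))
    if (co[1, ax] < 0) co[, ax] <- -co[, ax]
  rownames(co) <- qm$samples
  list(coords = co, dist = d)
}

#' Link each distal enhancer-like element to its nearest gene
#'
#' The linked gene is the protein-coding gene whose promoter
#' (+/-2000 bp of TSS) has the smallest edge-to-edge distance to the
#' dELS while not overlapping it (a dELS lies > 2 kb from every TSS, so
#' an overlap would contradict its class). Distance ties go to the gene
#' with the smaller promoter start, then the lexicographically smaller
#' id. dELS with no eligible gene on their chromosome get an NA link.
#'
#' @param dels interval table of dELS
#' @param annotation a `GenomeAnnotation`
#' @return data.table: dELS coordinates, `gene_id`, `distance` (bp;
#'   NA when no eligible gene exists)
#' @export
link_dels_to_genes <- function(dels, annotation) {
  dels <- as.data.table(dels)
  g <- annotation$genes[biotype == "protein_coding"]
  prom <- data.table(gene_id = g$gene_id, chrom = g$chrom,
                     start = pmax(g$tss - 2000, 0), end = g$tss + 2000)
  out <- copy(dels)
  out[, `:=`(gene_id = NA_character_, distance = NA_real_)]
  for (i in seq_len(nrow(out))) {
    pc <- prom[chrom == out$chrom[i]]
    if (nrow(pc) == 0L) next
    ## edge-to-edge gap; 0 when touching, negative (overlap) excluded
    gap <- pmax(pc$start - out$end[i], out$start[i] - pc$end)
    ok <- gap >= 0
    if (!any(ok)) next
    pc <- pc[ok]; gap <- gap[ok]
    ord <- order(gap, pc$start, pc$gene_id)
    out$gene_id[i] <- pc$gene_id[ord[1]]
    out$distance[i] <- gap[ord[1]]
  }
  out[]
}

#' Genes linked to the top-signal distal enhancer-like elements
#'
#' dELS are ranked by descending signal (ties broken by coordinate),
#' the strongest `n` are linked to their nearest genes, and the gene
#' list is deduplicated keeping each gene's best rank.
#'
#' @param qm `QuantMatrix` quantified over dELS for the chosen mark
#' @param sample column of `qm` to rank by (default first)
#' @param annotation a `GenomeAnnotation`
#' @param n number of top elements (all, with a warning, if fewer exist)
#' @return data.table: rank, dELS coordinates, signal, gene_id, distance
#' @export
top_ranked_dels <- function(qm, annotation, n = 2000, sample = 1L) {
  x <- qm$counts[, sample]
  if (n > length(x)) {
    warning(sprintf("requested top %d dELS but only %d available", n,
                    length(x)))
    n <- length(x)
  }
  r <- qm$regions
  ord <- order(-x, r$chrom, r$start)
  top <- ord[seq_len(n)]
  links <- link_dels_to_genes(r[top], annotation)
  links[, `:=`(signal = x[top], rank = seq_len(n))]
  links <- links[!is.na(gene_id)][!duplicated(gene_id)]
  links[]
}
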