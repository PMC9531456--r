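## Feature annotation and overlap-enrichment statistics -----------------------

#' Build the feature catalog used for peak annotation and enrichment
#'
#' Derives named feature interval sets from a `GenomeAnnotation`:
#' CGI/non-CGI promoters (+/-2000 bp of TSS; CGI if the window shares
#' >= 1 bp with a CpG island), 5'/3' UTRs (first/last 150 bp of the
#' first/last exon), exons, introns, `downstream` (3 kb past the gene
#' end) and `intergenic` (everything else), plus the raw CGI set.
#'
#' @param annotation a `GenomeAnnotation`
#' @param downstream_bp width of the downstream feature (default 3000)
#' @param utr_bp width taken from the terminal exons for the UTR
#'   features (default 150)
#' @return list of class `FeatureCatalog`: named interval sets,
#'   `genome_size`, and the promoter table with per-gene CGI flags
#' @export
feature_catalog <- function(annotation, downstream_bp = 3000,
                            utr_bp = 150) {
  g <- annotation$genes
  sizes <- annotation$chrom_sizes
  genome_size <- sum(sizes)
  prom <- data.table(gene_id = g$gene_id, chrom = g$chrom,
                     start = pmax(g$tss - 2000, 0),
                     end = pmin(g$tss + 2000, sizes[g$chrom]),
                     strand = g$strand, tss = g$tss)
  prom[, is_cgi := overlaps_any(prom, annotation$cgi)]

  ex <- annotation$exons
  utr5 <- list(); utr3 <- list()
  for (i in seq_len(nrow(g))) {
    exg <- ex[gene_id == g$gene_id[i]]
    if (nrow(exg) == 0L) next
    setorder(exg, start)
    first <- if (g$strand[i] == "+") exg[1] else exg[.N]
    last <- if (g$strand[i] == "+") exg[.N] else exg[1]
    u5e <- if (g$strand[i] == "+")
      c(first$start, min(first$start + utr_bp, first$end))
    else c(max(first$end - utr_bp, first$start), first$end)
    u3e <- if (g$strand[i] == "+")
      c(max(last$end - utr_bp, last$start), last$end)
    else c(last$start, min(last$start + utr_bp, last$end))
    utr5[[length(utr5) + 1L]] <- data.table(chrom = g$chrom[i],
                                            start = u5e[1], end = u5e[2])
    utr3[[length(utr3) + 1L]] <- data.table(chrom = g$chrom[i],
                                            start = u3e[1], end = u3e[2])
  }
  bind_iv <- function(l) {
    if (length(l) == 0L) return(intervals(character(), integer(), integer()))
    dt <- rbindlist(l)[start < end]
    if (nrow(dt) == 0L) return(intervals(character(), integer(), integer()))
    as_intervals(dt)
  }
  utr5 <- bind_iv(utr5); utr3 <- bind_iv(utr3)
  exon_iv <- if (nrow(ex)) as_intervals(ex[, .(chrom, start, end)])
             else intervals(character(), integer(), integer())
  body_iv <- as_intervals(g[, .(chrom, start = gene_start, end = gene_end)])
  intron_iv <- setdiff_intervals(body_iv, exon_iv)
  down_iv <- as_intervals(data.table(
    chrom = g$chrom,
    start = ifelse(g$strand == "+", g$gene_end,
                   pmax(g$gene_start - downstream_bp, 0)),
    end = ifelse(g$strand == "+",
                 pmin(g$gene_end + downstream_bp, sizes[g$chrom]),
                 g$gene_start))[start < end])
  genome_iv <- intervals(names(sizes), rep(0, length(sizes)),
                         as.numeric(sizes))
  covered <- union_peaks(list(prom[, .(chrom, start, end)], utr5, utr3,
                              exon_iv, intron_iv, down_iv))
  intergenic <- setdiff_intervals(genome_iv, covered)

  feats <- list(
    CGI_promoter = as_intervals(prom[is_cgi == TRUE, .(chrom, start, end)]),
    nonCGI_promoter = as_intervals(prom[is_cgi == FALSE,
                                        .(chrom, start, end)]),
    utr5 = utr5, exon = exon_iv, intron = intron_iv, utr3 = utr3,
    downstream = down_iv, intergenic = intergenic,
    CGI = annotation$cgi)
  structure(list(features = feats, genome_size = genome_size,
                 promoters = prom, chrom_sizes = sizes),
            class = "FeatureCatalog")
}

## A \ B on merged interval sets
setdiff_intervals <- function(a, b) {
  a <- merge_intervals(a)
  if (nrow(a) == 0L) return(a)
  b <- merge_intervals(b)
  if (nrow(b) == 0L) return(a)
  intervals_of(GenomicRanges::setdiff(gr_of(a), gr_of(b),
                                      ignore.strand = TRUE))
}

#' Assign one feature label per peak, with signed TSS distance
#'
#' Labels follow a fixed priority (promoter > 5'UTR > exon > intron >
#' 3'UTR > downstream > intergenic) with a >= 1 bp overlap rule, so each
#' peak gets exactly one label. `tss_distance` is from the peak midpoint
#' to the nearest TSS, signed by the strand of that gene (positive =
#' downstream of the TSS in gene orientation).
#'
#' @param peaks a `PeakSet` or interval table
#' @param catalog a [feature_catalog()]
#' @return data.table: peak coordinates, `feature` label, `tss_distance`,
#'   `nearest_gene`
#' @export
annotate_peaks <- function(peaks, catalog) {
  p <- as_intervals(data.table(chrom = peaks$chrom, start = peaks$start,
                               end = peaks$end))
  prio <- c("promoter", "utr5", "exon", "intron", "utr3", "downstream")
  label <- rep("intergenic", nrow(p))
  prom_all <- as_intervals(catalog$promoters[, .(chrom, start, end)])
  sets <- list(promoter = prom_all, utr5 = catalog$features$utr5,
               exon = catalog$features$exon,
               intron = catalog$features$intron,
               utr3 = catalog$features$utr3,
               downstream = catalog$features$downstream)
  unassigned <- rep(TRUE, nrow(p))
  for (f in prio) {
    if (!any(unassigned)) break
    hit <- overlaps_any(p, sets[[f]])
    label[unassigned & hit] <- f
    unassigned <- unassigned & !hit
  }
  mid <- floor((p$start + p$end) / 2)
  pr <- catalog$promoters
  tssd <- numeric(nrow(p)); ngene <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    same <- which(pr$chrom == p$chrom[i])
    if (length(same) == 0L) { tssd[i] <- NA; ngene[i] <- NA; next }
    d <- mid[i] - pr$tss[same]
    j <- same[which.min(abs(d))]
    raw <- mid[i] - pr$tss[j]
    tssd[i] <- if (pr$strand[j] == "+") raw else -raw
    ngene[i] <- pr$gene_id[j]
  }
  out <- data.table(chrom = p$chrom, start = p$start, end = p$end,
                    feature = label, tss_distance = tssd,
                    nearest_gene = ngene)
  out[]
}

#' Fold enrichment of a peak set over a genomic feature
#'
#' `overlap_bp * genome_size / (bp_peaks * bp_feature)`, all base-pair
#' sums taken on merged sets. Equals 1 in expectation for uniformly
#' placed peaks and exactly 1 when the feature is the whole genome.
#'
#' @param peaks,feature interval tables (non-empty after merging)
#' @param genome_size genome length, bp
#' @return fold enrichment (numeric)
#' @export
feature_fold_enrichment <- function(peaks, feature, genome_size) {
  bp_p <- intervals_bp(peaks); bp_f <- intervals_bp(feature)
  assert_that(bp_p > 0 && bp_f > 0,
              "peak and feature sets must be non-empty")
  overlap_bp(peaks, feature) * genome_size / (bp_p * bp_f)
}

#' Pairwise overlap enrichment between two interval sets
#'
#' `overlap_bp / (bp_setA * bp_setB)` on merged sets; symmetric and
#' invariant to fragmentation of either set. For heatmap display a
#' matrix of such values is column z-scaled with [zscale_columns()].
#'
#' @param set_a,set_b interval tables (non-empty after merging)
#' @return the enrichment ratio (numeric; 1/L for two identical sets of
#'   L bp)
#' @export
pairwise_set_enrichment <- function(set_a, set_b) {
  bp_a <- intervals_bp(set_a); bp_b <- intervals_bp(set_b)
  assert_that(bp_a > 0 && bp_b > 0, "both sets must be non-empty")
  overlap_bp(set_a, set_b) / (bp_a * bp_b)
}

#' Column-wise z-scaling for enrichment heatmap display
#' @param m numeric matrix
#' @return matrix with each column scaled to mean 0, sd 1 (constant
#'   columns become 0)
#' @export
zscale_columns <- function(m) {
  apply(m, 2, function(col) {
    s <- sd(col)
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

#' Fraction of reference elements covered by peaks
#'
#' Element-count fraction (not bp): the share of reference intervals
#' intersecting any peak by >= 1 bp.
#'
#' @param reference interval table (non-empty)
#' @param peaks interval table
#' @return fraction in [0, 1]
#' @export
fraction_covered <- function(reference, peaks) {
  reference <- as_intervals(reference)
  assert_that(nrow(reference) > 0L, "reference set is empty")
  mean(overlaps_any(reference, peaks))
}

#' Histogram of peak midpoints by signed distance to the nearest TSS
#'
#' @param peaks `PeakSet` or interval table
#' @param annotation a `GenomeAnnotation`
#' @param window half-width of the profile, bp
#' @param bin histogram bin width, bp
#' @return data.table with bin start/mid/end and peak counts; total
#'   count equals the number of peaks whose midpoint lies within
#'   +/-window of a TSS
#' @export
tss_profile <- function(peaks, annotation, window = 10000, bin = 500) {
  assert_that(window > 0 && bin > 0, "window and bin must be positive")
  catalog <- feature_catalog(annotation)
  ann <- annotate_peaks(peaks, catalog)
  d <- ann$tss_distance[!is.na(ann$tss_distance) &
                          abs(ann$tss_distance) <= window]
  breaks <- seq(-window, window, by = bin)
  if (tail(breaks, 1) < window) breaks <- c(breaks, window)
  h <- hist(d, breaks = breaks, plot = FALSE)
  data.table(bin_start = head(breaks, -1), bin_end = breaks[-1],
             bin_mid = (head(breaks, -1) + breaks[-1]) / 2,
             count = h$counts)
}
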