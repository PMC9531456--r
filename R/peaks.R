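## SEACR-style peak calling and region quantification -------------------------
##
## Sparse-background chromatin profiling (CUT&Tag/CUT&RUN) produces
## tracks where most of the genome is empty; the caller therefore scores
## maximal runs of contiguous non-zero coverage ("signal blocks") by
## their total signal (AUC = sum of value x width) and keeps the top
## fraction of blocks. This mirrors SEACR's stringent mode with a
## numeric threshold, read as nearest-rank selection of the top
## ceiling(f * B) blocks, with all blocks tied at the threshold AUC
## retained so the result is order-independent.

#' Average replicate tracks over the union of their breakpoints
#'
#' Piecewise-constant mean across replicates: at every segment of the
#' union breakpoint grid the value is the mean of the replicate values,
#' an absent replicate contributing 0. With a single input the track is
#' returned unchanged.
#'
#' @param tracks list of [signal_track()]s over a shared chromosome space
#' @return a [signal_track()]
#' @export
merge_replicates <- function(tracks) {
  assert_that(length(tracks) >= 1L, "need at least one track")
  if (length(tracks) == 1L) return(tracks[[1]])
  n <- length(tracks)
  all_dt <- rbindlist(lapply(seq_along(tracks), function(i)
    copy(tracks[[i]]$data)[, rep_id := i]))
  sizes <- Reduce(function(a, b) a %||% b,
                  lapply(tracks, function(t) t$chrom_sizes))
  out <- all_dt[, {
    bp <- sort(unique(c(start, end)))
    seg_s <- bp[-length(bp)]; seg_e <- bp[-1]
    tot <- numeric(length(seg_s))
    for (i in seq_len(n)) {
      ti <- .SD[rep_id == i]
      if (nrow(ti)) {
        idx <- findInterval(seg_s, ti$start)
        hit <- idx >= 1L & seg_s < ti$end[pmax(idx, 1L)]
        tot[hit] <- tot[hit] + ti$value[idx[hit]]
      }
    }
    list(start = seg_s, end = seg_e, value = tot / n)
  }, by = chrom]
  signal_track(out[value > 0], sizes)
}

#' Call peaks as top-AUC signal blocks (SEACR-style stringent mode)
#'
#' Blocks are maximal runs of contiguous (gap 0) non-zero intervals.
#' Each block is scored by AUC = sum(value x width); the
#' `ceiling(top_fraction x B)` highest-AUC blocks are retained
#' (nearest-rank; AUC ties at the cut are all kept). The summit is the
#' midpoint of the block's highest-valued interval.
#'
#' @param track a [signal_track()]
#' @param top_fraction fraction of blocks to keep, default 0.01 (top 1%)
#' @param sample optional sample label stored on the result
#' @return a `PeakSet`: data.table with chrom, start, end, name, auc,
#'   max_value, summit; attributes `sample` and `top_fraction`
#' @export
call_peaks_stringent <- function(track, top_fraction = 0.01, sample = NA) {
  assert_that(top_fraction > 0 && top_fraction <= 1,
              "top_fraction must be in (0, 1]")
  dt <- track$data
  if (nrow(dt) == 0L) return(empty_peakset(sample, top_fraction))
  dt <- copy(dt)[, block := cumsum(c(1L, start[-1] != end[-.N])), by = chrom]
  blocks <- dt[, .(start = start[1], end = end[.N],
                   auc = sum(value * (end - start)),
                   max_value = max(value),
                   summit = {
                     i <- which.max(value)
                     floor((start[i] + end[i]) / 2)
                   }),
               by = .(chrom, block)]
  keep_n <- top_n_of(nrow(blocks), top_fraction)
  thr <- sort(blocks$auc, decreasing = TRUE)[keep_n]
  peaks <- blocks[auc >= thr]
  setkey(peaks, chrom, start)
  peaks[, name := sprintf("peak%05d", .I)]
  out <- peaks[, .(chrom, start, end, name, auc, max_value, summit)]
  setattr(out, "class", c("PeakSet", class(out)))
  setattr(out, "sample", sample)
  setattr(out, "top_fraction", top_fraction)
  out[]
}

empty_peakset <- function(sample = NA, top_fraction = NA) {
  out <- data.table(chrom = character(), start = numeric(), end = numeric(),
                    name = character(), auc = numeric(),
                    max_value = numeric(), summit = numeric())
  setattr(out, "class", c("PeakSet", class(out)))
  setattr(out, "sample", sample)
  setattr(out, "top_fraction", top_fraction)
  out[]
}

#' Drop peaks overlapping a blacklist by at least 1 bp
#' @param peaks a `PeakSet`
#' @param blacklist interval table of excluded regions
#' @return filtered `PeakSet` (attributes preserved)
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (nrow(peaks) == 0L || is.null(blacklist) || nrow(blacklist) == 0L)
    return(peaks)
  hit <- overlaps_any(peaks[, .(chrom, start, end)], blacklist)
  out <- peaks[!hit]
  setattr(out, "class", class(peaks))
  setattr(out, "sample", attr(peaks, "sample"))
  setattr(out, "top_fraction", attr(peaks, "top_fraction"))
  out[]
}

#' Merge peak sets into a master (union) peak list
#' @param peaksets list of `PeakSet`s or interval tables
#' @return merged `intervals` (sorted, non-overlapping)
#' @export
union_peaks <- function(peaksets) {
  if (inherits(peaksets, "data.frame")) peaksets <- list(peaksets)
  assert_that(length(peaksets) >= 1L, "need at least one peak set")
  all_iv <- rbindlist(lapply(peaksets, function(p)
    data.table(chrom = p$chrom, start = p$start, end = p$end)))
  if (nrow(all_iv) == 0L)
    return(intervals(character(), integer(), integer()))
  merge_intervals(all_iv)
}

#' Genome-wide fixed-width tiles
#' @param chrom_sizes named vector of chromosome lengths
#' @param tile tile width, bp (3000 for sample-clustering bins, 200 for
#'   chromatin-state bins)
#' @return `intervals` partitioning each chromosome
#' @export
tile_genome <- function(chrom_sizes, tile = 3000) {
  assert_that(tile > 0, "tile width must be positive")
  dt <- rbindlist(lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    s <- seq(0, len - 1e-9, by = tile)
    data.table(chrom = ch, start = s, end = pmin(s + tile, len))
  }))
  as_intervals(dt)
}

#' Quantify signal over regions for a set of samples
#'
#' count(region, sample) = total signal (value x width) of the track
#' intersected with the region; the library size is the genome-wide
#' total of the track, so tile counts over a full partition sum exactly
#' to the library size.
#'
#' @param tracks named list of [signal_track()]s (names become samples)
#' @param regions interval table; regions must lie within the tracks'
#'   chromosome bounds when sizes are attached
#' @return a `QuantMatrix`: list(regions, counts, samples, normalization,
#'   lib_sizes, lengths)
#' @export
quantify <- function(tracks, regions) {
  assert_that(length(tracks) >= 1L, "need at least one track")
  if (is.null(names(tracks)))
    names(tracks) <- paste0("sample", seq_along(tracks))
  regions <- as_intervals(regions)
  for (t in tracks) {
    if (!is.null(t$chrom_sizes)) {
      bad <- regions[!(chrom %in% names(t$chrom_sizes)) |
                       end > t$chrom_sizes[chrom], which = TRUE]
      assert_that(length(bad) == 0L,
                  "region outside chromosome bounds (row %d)",
                  if (length(bad)) bad[1] else 0L)
    }
  }
  rgr <- gr_of(regions)
  counts <- vapply(tracks, function(t) {
    if (nrow(t$data) == 0L) return(numeric(length(rgr)))
    tgr <- gr_of(t$data)
    hits <- GenomicRanges::findOverlaps(rgr, tgr)
    if (length(hits) == 0L) return(numeric(length(rgr)))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(IRanges::pintersect(rgr[q], tgr[s]))
    v <- t$data$value[s] * w
    out <- numeric(length(rgr))
    agg <- tapply(v, q, sum)
    out[as.integer(names(agg))] <- agg
    out
  }, numeric(length(rgr)))
  counts <- matrix(counts, nrow = length(rgr),
                   dimnames = list(NULL, names(tracks)))
  structure(list(regions = regions, counts = counts,
                 samples = names(tracks), normalization = "raw",
                 lib_sizes = vapply(tracks, track_total, 0),
                 lengths = regions$end - regions$start),
            class = "QuantMatrix")
}

#' Normalize a raw QuantMatrix
#'
#' CPM = count x 1e6 / library size; RPKM additionally divides by the
#' region length in kb (count x 1e9 / (library x length)); the log2
#' variants apply log2(x + pseudocount) to the corresponding linear
#' normalization.
#'
#' @param qm a raw `QuantMatrix`
#' @param mode one of "CPM", "RPKM", "log2CPM", "log2RPKM"
#' @param pseudocount added before log2 (default 1, so log2CPM of 0 is 0)
#' @return the normalized `QuantMatrix`
#' @export
normalize_quant <- function(qm, mode = c("CPM", "RPKM", "log2CPM",
                                         "log2RPKM"),
                            pseudocount = 1) {
  mode <- match.arg(mode)
  assert_that(qm$normalization == "raw", "input must be a raw QuantMatrix")
  assert_that(all(qm$lib_sizes > 0), "zero library size")
  cpm <- sweep(qm$counts, 2, qm$lib_sizes, "/") * 1e6
  x <- switch(mode,
    CPM = cpm,
    log2CPM = log2(cpm + pseudocount),
    RPKM = {
      assert_that(all(qm$lengths > 0), "RPKM requires region lengths")
      sweep(qm$counts, 2, qm$lib_sizes, "/") * 1e9 / qm$lengths
    },
    log2RPKM = {
      assert_that(all(qm$lengths > 0), "RPKM requires region lengths")
      log2(sweep(qm$counts, 2, qm$lib_sizes, "/") * 1e9 / qm$lengths +
             pseudocount)
    })
  out <- qm
  out$counts <- x
  out$normalization <- mode
  out
}

#' Write a QuantMatrix as TSV (region coordinates + one column per sample)
#' @param qm `QuantMatrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_quant <- function(qm, path) {
  dt <- data.table(region_id = sprintf("r%06d", seq_len(nrow(qm$regions))),
                   chrom = qm$regions$chrom, start = qm$regions$start,
                   end = qm$regions$end)
  dt <- cbind(dt, as.data.table(qm$counts))
  write_tsv(dt, path)
}

#' Write a PeakSet as BED6+2 (name, auc score, strand, max_value, summit)
#' @param peaks `PeakSet`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_peaks <- function(peaks, path) {
  out <- data.table(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, name = peaks$name,
                    score = peaks$auc, strand = ".",
                    max_value = peaks$max_value, summit = peaks$summit)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE, scipen = 50)
  invisible(path)
}
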