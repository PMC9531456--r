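## Interval and track containers ---------------------------------------------
##
## All coordinates are 0-based half-open ([start, end)), the BED/bedGraph
## convention; conversion to the 1-based closed convention of
## GenomicRanges happens only inside gr_of()/intervals_of() and never
## leaks. Chromosome names are taken verbatim: "chr1" and "1" are
## different sequences and mixing them is an error, not a silent zero.

#' Construct a validated interval table
#'
#' The universal container for genomic interval sets: a `data.table` with
#' columns `chrom`, `start`, `end` and optionally `name`, `score`,
#' `strand`. Coordinates are 0-based half-open.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors, 0-based half-open
#' @param name,score,strand optional annotation columns
#' @return a `data.table` of class `intervals`, sorted by (chrom, start)
#' @export
intervals <- function(chrom, start, end, name = NULL, score = NULL,
                      strand = NULL) {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end))
  if (!is.null(name)) dt[, name := as.character(name)]
  if (!is.null(score)) dt[, score := as.numeric(score)]
  if (!is.null(strand)) dt[, strand := as.character(strand)]
  validate_intervals(dt)
  setkey(dt, chrom, start)
  setattr(dt, "class", c("intervals", class(dt)))
  dt[]
}

validate_intervals <- function(dt) {
  assert_that(all(c("chrom", "start", "end") %in% names(dt)),
              "interval table needs chrom/start/end columns")
  assert_that(!anyNA(dt$chrom) && all(nzchar(dt$chrom)),
              "empty chromosome name")
  bad <- which(!(dt$start >= 0 & dt$start < dt$end))
  assert_that(length(bad) == 0L,
              "invalid interval (need 0 <= start < end) at row %d",
              if (length(bad)) bad[1] else 0L)
  if ("strand" %in% names(dt)) {
    assert_that(all(dt$strand %in% c("+", "-", ".")),
                "strand must be one of '+', '-', '.'")
  }
  invisible(dt)
}

as_intervals <- function(x) {
  if (inherits(x, "intervals")) return(x)
  intervals(x$chrom, x$start, x$end,
            name = x$name %||% NULL, score = x$score %||% NULL,
            strand = if ("strand" %in% names(x)) x$strand else NULL)
}

## 0-based half-open -> GRanges (1-based closed); BED "." becomes "*"
gr_of <- function(x) {
  s <- if ("strand" %in% names(x)) sub(".", "*", x$strand, fixed = TRUE)
       else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = s)
}

## GRanges -> 0-based half-open interval table
intervals_of <- function(gr) {
  if (length(gr) == 0L)
    return(intervals(character(), integer(), integer()))
  intervals(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1, GenomicRanges::end(gr))
}

#' Merge an interval set (union of overlapping or book-ended intervals)
#'
#' All base-pair sums in the enrichment formulas are defined on merged
#' sets, so that fragmented or internally overlapping inputs give the
#' same answer as their union.
#'
#' @param x interval table
#' @return merged, sorted `intervals`
#' @export
merge_intervals <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0L) return(x)
  intervals_of(GenomicRanges::reduce(gr_of(x)))
}

#' Total base pairs covered by an interval set (after merging)
#' @param x interval table
#' @return numeric, bp
#' @export
intervals_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

#' Base pairs shared by two interval sets
#'
#' Each set is merged internally, then the total length of the
#' intersection is returned. Symmetric in its arguments; a single shared
#' base pair counts.
#'
#' @param a,b interval tables
#' @return numeric, bp of overlap
#' @export
overlap_bp <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ov <- GenomicRanges::intersect(gr_of(a), gr_of(b), ignore.strand = TRUE)
  sum(GenomicRanges::width(ov))
}

#' Which rows of one interval set intersect another by >= 1 bp
#' @param x,y interval tables
#' @return logical vector along the rows of `x`
#' @export
overlaps_any <- function(x, y) {
  x <- as_intervals(x)
  if (nrow(x) == 0L) return(logical(0))
  y <- as_intervals(y)
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  IRanges::overlapsAny(gr_of(x), gr_of(y), ignore.strand = TRUE)
}

## SignalTrack ---------------------------------------------------------------

#' Construct a SignalTrack
#'
#' bedGraph-semantics coverage: per chromosome an ordered set of
#' non-overlapping intervals with a non-negative value. Zero-valued rows
#' are dropped (absence of an interval means zero) and adjacent
#' equal-valued intervals are fused, so every track has one canonical
#' representation.
#'
#' @param dt data with chrom/start/end/value columns
#' @param chrom_sizes named numeric vector of chromosome lengths (bp);
#'   optional, but required by operations that tile the genome
#' @return object of class `SignalTrack`
#' @export
signal_track <- function(dt, chrom_sizes = NULL) {
  dt <- data.table(chrom = as.character(dt$chrom),
                   start = as.numeric(dt$start),
                   end = as.numeric(dt$end),
                   value = as.numeric(dt$value))
  assert_that(!anyNA(dt$value) && all(dt$value >= 0),
              "SignalTrack values must be non-negative")
  bad <- which(dt$start >= dt$end)
  assert_that(length(bad) == 0L, "start >= end at row %d",
              if (length(bad)) bad[1] else 0L)
  dt <- dt[value > 0]
  setkey(dt, chrom, start)
  if (nrow(dt) > 1L) {
    ov <- dt[, any(start[-1] < end[-.N]), by = chrom]$V1
    assert_that(!any(ov), "overlapping intervals within a chromosome")
    ## fuse book-ended runs with identical value
    dt[, run := cumsum(c(1L, (start[-1] != end[-.N]) |
                              (value[-1] != value[-.N]))), by = chrom]
    dt <- dt[, .(start = start[1], end = end[.N], value = value[1]),
             by = .(chrom, run)][, run := NULL][]
    setkey(dt, chrom, start)
  }
  if (!is.null(chrom_sizes)) {
    assert_that(!is.null(names(chrom_sizes)),
                "chrom_sizes must be a named vector")
    unknown <- setdiff(dt$chrom, names(chrom_sizes))
    assert_that(length(unknown) == 0L, "unknown chromosome '%s'",
                if (length(unknown)) unknown[1] else "")
    over <- dt[end > chrom_sizes[chrom], which = TRUE]
    assert_that(length(over) == 0L, "interval beyond chromosome end (row %d)",
                if (length(over)) over[1] else 0L)
  }
  structure(list(data = dt, chrom_sizes = chrom_sizes),
            class = "SignalTrack")
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack: %d intervals on %d chromosome(s), total signal %.4g\n",
              nrow(x$data), length(unique(x$data$chrom)), track_total(x)))
  invisible(x)
}

#' Total signal mass of a track (sum of value x width; the library size)
#' @param track a [signal_track()]
#' @return numeric
#' @export
track_total <- function(track) {
  with(track$data, sum(value * (end - start)))
}

#' Read a bedGraph file into a SignalTrack
#'
#' Four whitespace-delimited columns (chrom, start, end, value), 0-based
#' half-open. Zero-valued rows are dropped; malformed rows fail with
#' their line number; overlapping rows are rejected.
#'
#' @param path file path
#' @param chrom_sizes optional named vector; when given, intervals must
#'   lie within the named chromosomes
#' @return a [signal_track()]
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  dt <- if (file.size(path) == 0) data.table()
        else data.table::fread(path, header = FALSE, sep = "\t",
                               colClasses = list(character = 1),
                               fill = TRUE, blank.lines.skip = TRUE)
  if (nrow(dt) == 0L)
    return(signal_track(data.table(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()),
                        chrom_sizes))
  assert_that(ncol(dt) >= 4L, "bedGraph needs 4 columns, got %d", ncol(dt))
  setnames(dt, 1:4, c("chrom", "start", "end", "value"))
  first_bad <- function(mask) if (any(mask)) which(mask)[1] else 0L
  ln <- first_bad(is.na(dt$start) | is.na(dt$end) | is.na(dt$value))
  if (ln) stopf("%s: unparseable numeric field at line %d", path, ln)
  ln <- first_bad(dt$start < 0 | dt$start >= dt$end)
  if (ln) stopf("%s: invalid interval at line %d (start %s, end %s)",
                path, ln, dt$start[ln], dt$end[ln])
  ln <- first_bad(dt$value < 0)
  if (ln) stopf("%s: negative value at line %d", path, ln)
  if (!is.null(chrom_sizes)) {
    ln <- first_bad(!(dt$chrom %in% names(chrom_sizes)))
    if (ln) stopf("%s: unknown chromosome '%s' at line %d",
                  path, dt$chrom[ln], ln)
  }
  signal_track(dt[, 1:4], chrom_sizes)
}

#' Write a SignalTrack as bedGraph
#' @param track SignalTrack
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(track$data, path, sep = "\t", col.names = FALSE,
                     quote = FALSE, scipen = 50)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path file path
#' @param n_fields expected field count (3 or 6); `NULL` autodetects
#' @return an `intervals` table (with name/score/strand when BED6)
#' @export
read_bed <- function(path, n_fields = NULL) {
  dt <- if (file.size(path) == 0) data.table()
        else data.table::fread(path, header = FALSE, sep = "\t",
                               colClasses = list(character = 1),
                               blank.lines.skip = TRUE)
  if (nrow(dt) == 0L) return(intervals(character(), integer(), integer()))
  nf <- n_fields %||% min(ncol(dt), 6L)
  assert_that(ncol(dt) >= nf && nf %in% c(3L, 4L, 5L, 6L),
              "BED with %d fields requested but file has %d columns",
              nf, ncol(dt))
  bad <- which(is.na(dt[[2]]) | is.na(dt[[3]]) | dt[[2]] < 0 |
                 dt[[2]] >= dt[[3]])
  assert_that(length(bad) == 0L, "%s: malformed coordinates at line %d",
              path, if (length(bad)) bad[1] else 0L)
  intervals(dt[[1]], dt[[2]], dt[[3]],
            name = if (nf >= 4L) as.character(dt[[4]]) else NULL,
            score = if (nf >= 5L) suppressWarnings(as.numeric(dt[[5]])) else NULL,
            strand = if (nf >= 6L) as.character(dt[[6]]) else NULL)
}

#' Write an interval table as BED (3 or 6 columns)
#' @param x interval table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  cols <- c("chrom", "start", "end")
  if (any(c("name", "score", "strand") %in% names(x))) {
    out <- data.table(chrom = x$chrom, start = x$start, end = x$end,
                      name = x$name %||% ".",
                      score = x$score %||% 0,
                      strand = if ("strand" %in% names(x)) x$strand else ".")
  } else out <- x[, cols, with = FALSE]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE,
                     quote = FALSE, scipen = 50)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with chrom and size columns, no header
#' @return named numeric vector
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  assert_that(ncol(dt) >= 2L, "chromosome sizes file needs 2 columns")
  setNames(as.numeric(dt[[2]]), dt[[1]])
}

#' Uniformly re-place intervals on the genome, preserving widths
#'
#' Null model for the fold-enrichment statistics: each interval keeps its
#' length and is dropped uniformly at random on a chromosome chosen with
#' probability proportional to its placeable length.
#'
#' @param x interval table
#' @param chrom_sizes named vector of chromosome lengths
#' @return shuffled `intervals`
#' @export
shuffle_intervals <- function(x, chrom_sizes) {
  x <- as_intervals(x)
  if (nrow(x) == 0L) return(x)
  w <- x$end - x$start
  assert_that(all(w <= max(chrom_sizes)), "interval longer than every chromosome")
  probs <- pmax(chrom_sizes - max(w), 0)
  chroms <- sample(names(chrom_sizes), length(w), replace = TRUE,
                   prob = probs / sum(probs))
  start <- floor(runif(length(w)) * (chrom_sizes[chroms] - w))
  intervals(chroms, start, start + w)
}
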