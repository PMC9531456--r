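#' @import data.table
#' @importFrom stats ppois rpois rnorm runif cor cor.test wilcox.test
#'   p.adjust kmeans dnbinom dbinom setNames sd var quantile cmdscale dist
#' @importFrom stats median as.dist
#' @importFrom utils head tail
#' @importFrom graphics hist
#' @useDynLib epimark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Used so that every (tissue, mark, replicate) stream gets its own RNG
#' stream while remaining a pure function of the master seed. Kept below
#' 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param ... character or numeric labels identifying the stream
#' @return an integer seed
#' @export
sub_seed <- function(seed, ...) {
  labs <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labs)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

## Nearest-rank count for "top fraction" selection: ceiling(f * n), >= 1
## whenever n >= 1.
top_n_of <- function(n, fraction) {
  if (n == 0L) return(0L)
  max(1L, as.integer(ceiling(fraction * n)))
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}
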