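## Chromatin-state discovery: binarization + multivariate Bernoulli HMM -------
##
## Coverage tracks are binarized into 200-bp bins by a Poisson upper-tail
## test against the genome-wide mean bin count, then a K-state hidden
## Markov model with independent Bernoulli emissions per channel is fit
## by Baum-Welch EM. A channel is normally one histone mark within a
## tissue; in the across-tissues mode it is the same mark in different
## tissues, which turns tissue specificity of the mark into state
## structure.

#' Binarize one track into fixed-width bins by a Poisson tail test
#'
#' Per-bin count c = rounded total signal (value x width) within the
#' bin; lambda = genome-wide mean of c; a bin is called present (1) iff
#' the upper-tail probability P(X >= c | lambda) is at most
#' `p_threshold`. An all-zero track yields an all-zero vector.
#'
#' @param track a [signal_track()] with chromosome sizes attached
#' @param bin_size bin width, bp (default 200)
#' @param p_threshold Poisson upper-tail cutoff (default 1e-4)
#' @return list: `bins` (interval table), `counts`, `binary` (0/1),
#'   `lambda`, `bin_size`
#' @export
binarize_track <- function(track, bin_size = 200, p_threshold = 1e-4) {
  assert_that(!is.null(track$chrom_sizes),
              "binarization needs chromosome sizes on the track")
  bins <- tile_genome(track$chrom_sizes, bin_size)
  qm <- quantify(list(x = track), bins)
  counts <- round(qm$counts[, 1])
  lambda <- mean(counts)
  binary <- if (lambda == 0) integer(length(counts))
            else as.integer(counts >= 1 &
                              ppois(counts - 1, lambda,
                                    lower.tail = FALSE) <= p_threshold)
  list(bins = bins, counts = counts, binary = binary, lambda = lambda,
       bin_size = bin_size)
}

#' Binarize a set of channel tracks onto a common bin grid
#'
#' @param tracks named list of [signal_track()]s; names become channel
#'   names (marks, or tissues in the across-tissues mode)
#' @param bin_size,p_threshold see [binarize_track()]
#' @return list of class `BinarizedTracks`: `bins`, binary `matrix`
#'   (bins x channels), `channels`, `lambda` per channel, `bin_size`
#' @export
binarize_tracks <- function(tracks, bin_size = 200, p_threshold = 1e-4) {
  assert_that(length(tracks) >= 1L && !is.null(names(tracks)),
              "need a named list of tracks")
  per <- lapply(tracks, binarize_track, bin_size = bin_size,
                p_threshold = p_threshold)
  bins <- per[[1]]$bins
  mat <- vapply(per, function(x) x$binary, integer(nrow(bins)))
  mat <- matrix(mat, nrow = nrow(bins),
                dimnames = list(NULL, names(tracks)))
  structure(list(bins = bins, matrix = mat, channels = names(tracks),
                 lambda = vapply(per, function(x) x$lambda, 0),
                 bin_size = bin_size),
            class = "BinarizedTracks")
}

## per-position log emission probabilities under independent Bernoulli
## channels: logB[t, k] = sum_m x_tm log e_km + (1 - x_tm) log(1 - e_km)
log_emission <- function(X, E) {
  E <- pmin(pmax(E, 1e-6), 1 - 1e-6)
  X %*% t(log(E)) + (1 - X) %*% t(log(1 - E))
}

## split the bin matrix into per-chromosome sequences
split_sequences <- function(data) {
  idx <- split(seq_len(nrow(data$bins)), data$bins$chrom)
  lapply(idx, function(i) data$matrix[i, , drop = FALSE])
}

#' Fit a multivariate Bernoulli-emission HMM by Baum-Welch EM
#'
#' Channels are independent given the state; chromosomes are treated as
#' independent sequences sharing parameters. Initialization is k-means
#' on the binary bin patterns plus seeded random perturbations
#' (`n_restarts` restarts, best final log-likelihood wins). The
#' log-likelihood trace is non-decreasing within each restart (EM
#' guarantee).
#'
#' @param data a [binarize_tracks()] result
#' @param K number of states (>= 1, at most the number of bins)
#' @param seed RNG seed for initialization
#' @param max_iter maximum EM iterations
#' @param tol stop when the log-likelihood improves by less than this
#' @param n_restarts number of seeded restarts
#' @return object of class `ChromHMMModel`: `K`, `emissions` (K x M),
#'   `transitions` (K x K), `initial`, `loglik_trace`, `channels`
#' @export
fit_hmm <- function(data, K, seed = 1L, max_iter = 200L, tol = 1e-4,
                    n_restarts = 3L) {
  assert_that(K >= 1L, "K must be >= 1")
  X <- data$matrix
  assert_that(K <= nrow(X), "K exceeds the number of bins")
  M <- ncol(X)
  seqs <- split_sequences(data)

  if (K == 1L) {
    ## closed form: single state, emissions are channel means
    e <- matrix(colMeans(X), nrow = 1,
                dimnames = list(NULL, data$channels))
    ll <- sum(log_emission(X, e))
    return(structure(list(K = 1L, emissions = e,
                          transitions = matrix(1, 1, 1),
                          initial = 1, loglik_trace = ll,
                          channels = data$channels),
                     class = "ChromHMMModel"))
  }

  run_em <- function(E0) {
    E <- E0
    A <- matrix(0.05 / (K - 1), K, K); diag(A) <- 0.95
    pi0 <- rep(1 / K, K)
    trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      gsumX <- matrix(0, K, M); gsum <- numeric(K)
      xi_tot <- matrix(0, K, K); pi_acc <- numeric(K)
      ll <- 0
      for (s in seqs) {
        logB <- log_emission(s, E)
        fb <- hmm_forward_backward(logB, A, pi0)
        ll <- ll + fb$loglik
        gsumX <- gsumX + t(fb$gamma) %*% s
        gsum <- gsum + colSums(fb$gamma)
        xi_tot <- xi_tot + fb$xi
        pi_acc <- pi_acc + fb$gamma[1, ]
      }
      trace <- c(trace, ll)
      if (is.finite(prev) && (ll - prev) < tol) break
      prev <- ll
      E <- gsumX / pmax(gsum, 1e-300)
      E <- pmin(pmax(E, 1e-6), 1 - 1e-6)
      rs <- rowSums(xi_tot)
      A <- xi_tot / pmax(rs, 1e-300)
      A[rs == 0, ] <- 1 / K
      pi0 <- pi_acc / sum(pi_acc)
    }
    list(E = E, A = A, pi = pi0, trace = trace)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(sub_seed(seed, "hmm-init", K, r))
    E0 <- tryCatch({
      km <- suppressWarnings(kmeans(X, centers = K, nstart = 1,
                                    iter.max = 20))
      km$centers
    }, error = function(e) matrix(runif(K * M), K, M))
    if (r > 1L) E0 <- E0 + matrix(rnorm(K * M, 0, 0.1), K, M)
    E0 <- pmin(pmax(E0, 0.02), 0.98)
    fit <- run_em(E0)
    if (is.null(best) || tail(fit$trace, 1) > tail(best$trace, 1))
      best <- fit
  }
  colnames(best$E) <- data$channels
  structure(list(K = as.integer(K), emissions = best$E,
                 transitions = best$A, initial = best$pi,
                 loglik_trace = best$trace, channels = data$channels),
            class = "ChromHMMModel")
}

#' @export
print.ChromHMMModel <- function(x, ...) {
  cat(sprintf("ChromHMMModel: %d states x %d channels, final loglik %.2f\n",
              x$K, length(x$channels), tail(x$loglik_trace, 1)))
  print(round(x$emissions, 3))
  invisible(x)
}

#' Segment binarized tracks with a fitted model
#'
#' Default decoding labels each bin with the state of maximal
#' forward-backward posterior probability (matching the behavior of the
#' standard segmentation tools); Viterbi decoding of the jointly most
#' probable path is available behind `method = "viterbi"`.
#'
#' @param model a `ChromHMMModel`
#' @param data a [binarize_tracks()] result with the same channels
#' @param method "posterior" (default) or "viterbi"
#' @return data.table of class `StateSegmentation`: bin coordinates,
#'   `state` (1..K), `posterior` (max posterior probability; NA for
#'   viterbi)
#' @export
segment_states <- function(model, data, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  assert_that(identical(model$channels, data$channels),
              "model channels do not match the binarized data")
  idx <- split(seq_len(nrow(data$bins)), data$bins$chrom)
  state <- integer(nrow(data$bins)); post <- rep(NA_real_, nrow(data$bins))
  for (i in idx) {
    s <- data$matrix[i, , drop = FALSE]
    logB <- log_emission(s, model$emissions)
    if (model$K == 1L) {
      state[i] <- 1L; post[i] <- 1
    } else if (method == "posterior") {
      fb <- hmm_forward_backward(logB, model$transitions, model$initial)
      state[i] <- max.col(fb$gamma, ties.method = "first")
      post[i] <- fb$gamma[cbind(seq_len(nrow(fb$gamma)), state[i])]
    } else {
      state[i] <- hmm_viterbi(logB, model$transitions, model$initial)
    }
  }
  out <- data.table(chrom = data$bins$chrom, start = data$bins$start,
                    end = data$bins$end, state = state, posterior = post)
  setattr(out, "class", c("StateSegmentation", class(out)))
  setattr(out, "K", model$K)
  out[]
}

#' Posterior state probabilities per bin (forward-backward)
#'
#' Exposed for verification: each row sums to 1.
#'
#' @param model a `ChromHMMModel`
#' @param data a [binarize_tracks()] result
#' @return matrix bins x K
#' @export
posterior_probabilities <- function(model, data) {
  assert_that(identical(model$channels, data$channels),
              "model channels do not match the binarized data")
  idx <- split(seq_len(nrow(data$bins)), data$bins$chrom)
  out <- matrix(NA_real_, nrow(data$bins), model$K)
  for (i in idx) {
    s <- data$matrix[i, , drop = FALSE]
    logB <- log_emission(s, model$emissions)
    if (model$K == 1L) out[i, 1] <- 1
    else out[i, ] <- hmm_forward_backward(logB, model$transitions,
                                          model$initial)$gamma
  }
  out
}

#' State-by-element overlap enrichment
#'
#' enrichment(k, e) = (fraction of state-k bins overlapping element set
#' e) / (fraction of all bins overlapping e); a bin overlaps an element
#' if they share >= 1 bp. Empty states yield NA rows.
#'
#' @param seg a [segment_states()] result
#' @param elements named list of interval tables
#' @return matrix K x length(elements)
#' @export
state_enrichment <- function(seg, elements) {
  K <- attr(seg, "K") %||% max(seg$state)
  bins <- as_intervals(seg[, .(chrom, start, end)])
  out <- matrix(NA_real_, K, length(elements),
                dimnames = list(paste0("state", seq_len(K)),
                                names(elements)))
  total <- nrow(bins)
  for (e in seq_along(elements)) {
    hit <- overlaps_any(bins, elements[[e]])
    base <- sum(hit) / total
    for (k in seq_len(K)) {
      nk <- sum(seg$state == k)
      if (nk == 0L || base == 0) next
      out[k, e] <- sum(hit[seg$state == k]) / nk / base
    }
  }
  out
}

#' Best emission correlation of each candidate state against a reference
#'
#' For model selection across K: every candidate state is compared to
#' all states of a reference model by Pearson correlation of emission
#' vectors; the per-state maximum is returned. Constant emission
#' vectors have undefined correlation and yield NA.
#'
#' @param candidate,reference `ChromHMMModel`s over the same channels
#' @return numeric vector, one entry per candidate state
#' @export
compare_models <- function(candidate, reference) {
  assert_that(identical(candidate$channels, reference$channels),
              "models have different channels")
  assert_that(length(candidate$channels) >= 2L,
              "emission correlation needs at least 2 channels")
  vapply(seq_len(candidate$K), function(k) {
    ek <- candidate$emissions[k, ]
    if (sd(ek) == 0) return(NA_real_)
    cors <- vapply(seq_len(reference$K), function(j) {
      ej <- reference$emissions[j, ]
      if (sd(ej) == 0) return(NA_real_)
      cor(ek, ej)
    }, 0)
    if (all(is.na(cors))) NA_real_ else max(cors, na.rm = TRUE)
  }, 0)
}

#' Match states between two emission matrices (label switching)
#'
#' Finds the state permutation maximizing the summed Pearson correlation
#' between matched emission rows; exhaustive over permutations for
#' K <= 7, greedy beyond. Used by recovery tests to undo label
#' switching.
#'
#' @param est,truth emission matrices with equal dimensions
#' @return integer permutation p with est[p[k], ] matched to truth[k, ]
#' @export
match_states <- function(est, truth) {
  K <- nrow(truth)
  assert_that(nrow(est) == K, "state counts differ")
  score <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    a <- est[i, ]; b <- truth[j, ]
    score[i, j] <- if (sd(a) == 0 || sd(b) == 0)
      -sum((a - b)^2) else cor(a, b) - sum((a - b)^2) * 1e-6
  }
  if (K <= 7L) {
    perms <- all_perms(K)
    best <- NULL; bestv <- -Inf
    for (p in perms) {
      v <- sum(score[cbind(p, seq_len(K))])
      if (v > bestv) { bestv <- v; best <- p }
    }
    best
  } else {
    p <- integer(K); used <- logical(K)
    for (j in order(-apply(score, 2, max))) {
      i <- order(-score[, j])
      i <- i[!used[i]][1]
      p[j] <- i; used[i] <- TRUE
    }
    p
  }
}

## all permutations of 1..n, by inserting n into each slot of each
## permutation of 1..n-1
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) for (pos in 0:(n - 1)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

#' Serialize a ChromHMMModel to JSON
#' @param model `ChromHMMModel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, channels = model$channels,
         emissions = unname(model$emissions),
         transitions = unname(model$transitions),
         initial = model$initial, loglik_trace = model$loglik_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ChromHMMModel from JSON written by [write_hmm_json()]
#' @param path JSON path
#' @return `ChromHMMModel`
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  em <- matrix(as.numeric(x$emissions), nrow = x$K,
               dimnames = list(NULL, x$channels))
  tr <- matrix(as.numeric(x$transitions), nrow = x$K)
  structure(list(K = as.integer(x$K), emissions = em, transitions = tr,
                 initial = x$initial, loglik_trace = x$loglik_trace,
                 channels = x$channels),
            class = "ChromHMMModel")
}
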