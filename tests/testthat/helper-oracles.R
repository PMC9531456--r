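# Independent oracles used by the tests. Deliberately naive: per-base
# membership counting, exhaustive path enumeration, O(n*m) scans. They
# never share code with the implementation paths they check.

# track from parallel vectors
mk_track <- function(chrom, start, end, value, sizes = NULL) {
  signal_track(data.table::data.table(chrom = chrom, start = start,
                                      end = end, value = value), sizes)
}

iv <- function(chrom, start, end, ...) intervals(chrom, start, end, ...)

# per-base boolean membership overlap on a small genome
oracle_overlap_bp <- function(a, b, genome_len = 10000,
                              chroms = unique(c(a$chrom, b$chrom))) {
  total <- 0
  for (ch in chroms) {
    in_a <- logical(genome_len); in_b <- logical(genome_len)
    aa <- a[a$chrom == ch, ]; bb <- b[b$chrom == ch, ]
    for (i in seq_len(nrow(aa))) in_a[(aa$start[i] + 1):aa$end[i]] <- TRUE
    for (i in seq_len(nrow(bb))) in_b[(bb$start[i] + 1):bb$end[i]] <- TRUE
    total <- total + sum(in_a & in_b)
  }
  total
}

# exhaustive posterior for a Bernoulli-emission HMM over all K^T paths
oracle_posteriors <- function(X, E, A, pi0) {
  T_ <- nrow(X); K <- nrow(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  probs <- apply(paths, 1, function(z) {
    p <- pi0[z[1]]
    for (t in seq_len(T_)) {
      em <- prod(ifelse(X[t, ] == 1, E[z[t], ], 1 - E[z[t], ]))
      p <- p * em
      if (t < T_) p <- p * A[z[t], z[t + 1]]
    }
    p
  })
  post <- matrix(0, T_, K)
  for (t in seq_len(T_)) for (k in seq_len(K))
    post[t, k] <- sum(probs[paths[, t] == k])
  post / rowSums(post)
}

# O(n*m) nearest non-overlapping promoter scan
oracle_link <- function(dels, genes) {
  out <- data.frame(gene_id = character(nrow(dels)),
                    distance = numeric(nrow(dels)))
  for (i in seq_len(nrow(dels))) {
    best <- NULL
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != dels$chrom[i]) next
      ps <- max(genes$tss[j] - 2000, 0); pe <- genes$tss[j] + 2000
      gap <- max(ps - dels$end[i], dels$start[i] - pe)
      if (gap < 0) next
      cand <- list(gene_id = genes$gene_id[j], distance = gap, start = ps)
      if (is.null(best) || gap < best$distance ||
          (gap == best$distance && (cand$start < best$start ||
             (cand$start == best$start && cand$gene_id < best$gene_id))))
        best <- cand
    }
    if (is.null(best)) {
      out$gene_id[i] <- NA; out$distance[i] <- NA
    } else {
      out$gene_id[i] <- best$gene_id; out$distance[i] <- best$distance
    }
  }
  out
}

# draw one sequence from a Bernoulli-emission HMM and wrap it in the
# container fit_hmm() consumes
simulate_hmm_data <- function(E, A, pi0, T_, seed = 1) {
  set.seed(seed)
  K <- nrow(E); M <- ncol(E)
  z <- integer(T_)
  z[1] <- sample.int(K, 1, prob = pi0)
  for (t in 2:T_) z[t] <- sample.int(K, 1, prob = A[z[t - 1], ])
  X <- matrix(rbinom(T_ * M, 1, E[z, ]), T_, M)
  channels <- paste0("ch", seq_len(M))
  colnames(X) <- channels
  data <- structure(list(
    bins = intervals(rep("chr1", T_), (seq_len(T_) - 1) * 200,
                     seq_len(T_) * 200),
    matrix = X, channels = channels,
    lambda = rep(NA_real_, M), bin_size = 200),
    class = "BinarizedTracks")
  list(data = data, states = z)
}

# brute-force Poisson upper tail P(X >= c) by pmf summation
oracle_pois_upper <- function(c, lambda, upto = 1000) {
  if (c <= 0) return(1)
  k <- 0:(c - 1)
  1 - sum(exp(-lambda) * lambda^k / factorial(k))
}
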