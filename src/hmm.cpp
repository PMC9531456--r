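#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one observation sequence.
//
// logB: T x K matrix of log emission probabilities per position/state.
// A: K x K row-stochastic transition matrix, pi: initial distribution.
// Returns log-likelihood, posterior state probabilities gamma (T x K),
// and the transition expectation sums xi (K x K). Per-position scaling
// keeps everything in linear space without underflow for sequences of
// 1e7+ bins.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K);
  // stabilize: exponentiate around the per-position max
  NumericVector rowmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    rowmax[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) stop("zero forward probability at position 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = acc * B(t, k);
      s += alpha(t, k);
    }
    if (s <= 0) stop("zero forward probability");
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j)
        acc += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = acc / c[t + 1];
    }
  }
  // posteriors and transition expectations
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double gs = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      gs += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= gs;
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j)
        xi(k, j) += alpha(t, k) * A(k, j) * B(t + 1, j) * beta(t + 1, j) /
                    c[t + 1];
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]) + rowmax[t];
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Viterbi decoding (log space).
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericMatrix A,
                          NumericVector pi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -std::numeric_limits<double>::infinity();
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : NEG) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = NEG; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + (A(j, k) > 0 ? std::log(A(j, k)) : NEG);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = NEG; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path + 1; // 1-based state labels
}
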