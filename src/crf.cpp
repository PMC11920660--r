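#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a linear-chain CRF.
// emis: T x K matrix of per-position log emission potentials.
// trans: K x K matrix of log transition potentials (row = previous tag).
// Returns log partition, node marginals (T x K) and expected transition
// counts (K x K) summed over positions.
// [[Rcpp::export]]
List crf_forward_backward(NumericMatrix emis, NumericMatrix trans) {
  const int T = emis.nrow(), K = emis.ncol();
  if (T == 0) stop("empty sentence");
  NumericMatrix M(T, K);            // exp(emis - rowmax), per row
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double mx = emis(t, 0);
    for (int k = 1; k < K; ++k) if (emis(t, k) > mx) mx = emis(t, k);
    shift[t] = mx;
    for (int k = 0; k < K; ++k) M(t, k) = std::exp(emis(t, k) - mx);
  }
  NumericMatrix Tr(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k) Tr(j, k) = std::exp(trans(j, k));

  NumericMatrix alpha(T, K), beta(T, K);
  NumericVector c(T);               // per-position scaling constants
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += M(0, k);
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) = M(0, k) / s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * Tr(j, k);
      a *= M(t, k);
      alpha(t, k) = a;
      s += a;
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double b = 0.0;
      for (int k = 0; k < K; ++k)
        b += Tr(j, k) * M(t + 1, k) * beta(t + 1, k);
      beta(t, j) = b / c[t + 1];
    }
  }
  double logZ = 0.0;
  for (int t = 0; t < T; ++t) logZ += std::log(c[t]) + shift[t];

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    double z = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      z += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= z;
  }
  NumericMatrix etr(K, K);
  for (int t = 0; t + 1 < T; ++t) {
    for (int j = 0; j < K; ++j) {
      const double aj = alpha(t, j);
      if (aj == 0.0) continue;
      for (int k = 0; k < K; ++k) {
        etr(j, k) += aj * Tr(j, k) * M(t + 1, k) * beta(t + 1, k) / c[t + 1];
      }
    }
  }
  return List::create(_["log_z"] = logZ, _["node_marginals"] = gamma,
                      _["expected_transitions"] = etr);
}

// Viterbi decoding. Ties are broken toward the smaller tag index, both in
// the backpointers and in the final argmax, so among equally scoring paths
// the one whose tag at the latest differing position comes earliest in the
// label order is returned.
// [[Rcpp::export]]
IntegerVector crf_viterbi_path(NumericMatrix emis, NumericMatrix trans) {
  const int T = emis.nrow(), K = emis.ncol();
  if (T == 0) stop("empty sentence");
  NumericMatrix delta(T, K);
  IntegerMatrix bp(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = emis(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      int arg = 0;
      double best = delta(t - 1, 0) + trans(0, k);
      for (int j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + trans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + emis(t, k);
      bp(t, k) = arg;
    }
  }
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int k = 1; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = bp(t, path[t]);
  return path + 1;  // 1-based tag indices for R
}
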