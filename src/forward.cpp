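#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for one observation sequence.
// dens: T x K matrix of per-bin emission densities (missing data already
//       contribute 1). trans: either a K x K matrix (homogeneous chain) or
//       a K x K x T array (slice t is the transition matrix used to move
//       INTO bin t; slice 0 is unused). delta: initial state distribution.
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix dens, NumericVector trans,
                          NumericVector delta) {
  const int T = dens.nrow(), K = dens.ncol();
  const bool homog = ((int) trans.size() == K * K);
  std::vector<double> alpha(K), tmp(K);
  double ll = 0.0, s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha[k] = delta[k] * dens(0, k);
    s += alpha[k];
  }
  if (s <= 0.0 || !std::isfinite(s)) return R_NegInf;
  for (int k = 0; k < K; ++k) alpha[k] /= s;
  ll += std::log(s);
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    const int off = homog ? 0 : K * K * t;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i)
        a += alpha[i] * trans[off + i + K * j];
      tmp[j] = a * dens(t, j);
      s += tmp[j];
    }
    if (s <= 0.0 || !std::isfinite(s)) return R_NegInf;
    for (int j = 0; j < K; ++j) alpha[j] = tmp[j] / s;
    ll += std::log(s);
  }
  return ll;
}

// Viterbi decoding in log space; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logdens, NumericVector logtrans,
                          NumericVector logdelta) {
  const int T = logdens.nrow(), K = logdens.ncol();
  const bool homog = ((int) logtrans.size() == K * K);
  NumericMatrix v(T, K);
  IntegerMatrix bp(T, K);
  for (int k = 0; k < K; ++k) v(0, k) = logdelta[k] + logdens(0, k);
  for (int t = 1; t < T; ++t) {
    const int off = homog ? 0 : K * K * t;
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double cand = v(t - 1, i) + logtrans[off + i + K * j];
        if (cand > best) { best = cand; arg = i; }
      }
      v(t, j) = best + logdens(t, j);
      bp(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (v(T - 1, k) > best) { best = v(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) {
    arg = bp(t, arg);
    path[t - 1] = arg;
  }
  return path + 1;  // 1-based states
}
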