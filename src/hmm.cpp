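#include <Rcpp.h>
using namespace Rcpp;

// Per-group log-sum-exp over a vector laid out in contiguous groups.
// starts are 0-based offsets, sizes the group lengths.
// [[Rcpp::export]]
NumericVector grp_logsumexp_cpp(NumericVector x, IntegerVector starts,
                                IntegerVector sizes) {
  int G = starts.size();
  NumericVector out(G);
  for (int g = 0; g < G; g++) {
    int s = starts[g], n = sizes[g];
    double m = R_NegInf;
    for (int i = 0; i < n; i++) if (x[s + i] > m) m = x[s + i];
    if (!R_FINITE(m)) { out[g] = m; continue; }
    double acc = 0.0;
    for (int i = 0; i < n; i++) acc += std::exp(x[s + i] - m);
    out[g] = m + std::log(acc);
  }
  return out;
}

// Scaled forward algorithm for one track.
// logdens: M x K matrix of per-step log state-dependent densities
//   (rows of zeros encode missing / excluded steps, i.e. identity P).
// gammas: K x K x M array; slice s (1-based s >= 2) moves the chain from
//   step s-1 to step s. Slice 1 is unused.
// delta: initial state distribution (stationary of the first slice's Gamma).
// Returns the negative log-likelihood contribution of the track.
// [[Rcpp::export]]
double forward_nll_cpp(NumericMatrix logdens, NumericVector gammas,
                       NumericVector delta) {
  int M = logdens.nrow(), K = logdens.ncol();
  std::vector<double> phi(K), tmp(K);
  double ll = 0.0;

  // step 1
  double m0 = R_NegInf;
  for (int k = 0; k < K; k++) if (logdens(0, k) > m0) m0 = logdens(0, k);
  if (!R_FINITE(m0)) return R_PosInf;
  double s0 = 0.0;
  for (int k = 0; k < K; k++) {
    phi[k] = delta[k] * std::exp(logdens(0, k) - m0);
    s0 += phi[k];
  }
  if (s0 <= 0.0 || !R_FINITE(s0)) return R_PosInf;
  ll += m0 + std::log(s0);
  for (int k = 0; k < K; k++) phi[k] /= s0;

  for (int s = 1; s < M; s++) {
    double ms = R_NegInf;
    for (int k = 0; k < K; k++) if (logdens(s, k) > ms) ms = logdens(s, k);
    if (!R_FINITE(ms)) return R_PosInf;
    const double *G = &gammas[(size_t)s * K * K];  // column-major K x K
    double ssum = 0.0;
    for (int j = 0; j < K; j++) {
      double v = 0.0;
      for (int i = 0; i < K; i++) v += phi[i] * G[i + j * K];
      tmp[j] = v * std::exp(logdens(s, j) - ms);
      ssum += tmp[j];
    }
    if (ssum <= 0.0 || !R_FINITE(ssum)) return R_PosInf;
    ll += ms + std::log(ssum);
    for (int k = 0; k < K; k++) phi[k] = tmp[k] / ssum;
  }
  return -ll;
}
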