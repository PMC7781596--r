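#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Yates permutation of idx[0..n-1] using R's RNG
static inline void shuffle_idx(std::vector<int>& idx, int lo, int hi) {
  for (int i = hi - 1; i > lo; --i) {
    int j = lo + (int)(unif_rand() * (i - lo + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// Jitter-corrected cross-covariance, one row per trial.
//
// a, b: trials x bins count matrices (10 ms bins canonically).
// block: bins per jitter block (5 bins = 50 ms). For each of n_shuffle
// surrogates the bins of each cell are independently permuted within each
// block; the mean surrogate cross-covariance is subtracted from the raw
// one, removing covariance due to rate dynamics slower than the block.
// Cross-covariance at lag l uses mean-subtracted counts and biased (1/B)
// normalization. Columns run lag = -max_lag..max_lag.
// [[Rcpp::export]]
NumericMatrix jitter_xcov_cpp(IntegerMatrix a, IntegerMatrix b, int block,
                              int n_shuffle, int max_lag) {
  const int ntr = a.nrow(), B = a.ncol(), L = max_lag, nl = 2 * L + 1;
  NumericMatrix out(ntr, nl);
  std::vector<double> am(B), bm(B), pa(B), pb(B), acc(nl), raw(nl);
  std::vector<int> ia(B), ib(B);
  GetRNGstate();
  for (int tr = 0; tr < ntr; ++tr) {
    double ma = 0, mb = 0;
    for (int t = 0; t < B; ++t) { ma += a(tr, t); mb += b(tr, t); }
    ma /= B; mb /= B;
    for (int t = 0; t < B; ++t) { am[t] = a(tr, t) - ma; bm[t] = b(tr, t) - mb; }
    for (int l = -L; l <= L; ++l) {
      double scv = 0;
      int t0 = std::max(0, -l), t1 = std::min(B, B - l);
      for (int t = t0; t < t1; ++t) scv += am[t] * bm[t + l];
      raw[l + L] = scv / B;
    }
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int s = 0; s < n_shuffle; ++s) {
      for (int t = 0; t < B; ++t) { ia[t] = t; ib[t] = t; }
      for (int b0 = 0; b0 < B; b0 += block) {
        int b1 = std::min(B, b0 + block);
        shuffle_idx(ia, b0, b1);
        shuffle_idx(ib, b0, b1);
      }
      for (int t = 0; t < B; ++t) { pa[t] = am[ia[t]]; pb[t] = bm[ib[t]]; }
      for (int l = -L; l <= L; ++l) {
        double scv = 0;
        int t0 = std::max(0, -l), t1 = std::min(B, B - l);
        for (int t = t0; t < t1; ++t) scv += pa[t] * pb[t + l];
        acc[l + L] += scv / B;
      }
    }
    for (int l = 0; l < nl; ++l)
      out(tr, l) = raw[l] - (n_shuffle > 0 ? acc[l] / n_shuffle : 0.0);
  }
  PutRNGstate();
  return out;
}
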