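#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Maximal circular-binary-segmentation t statistic over all valid arcs
// (i, j], comparing the arc mean against the mean of its complement.
// The common variance factor is omitted: it is invariant under permutation
// of the data, so both the argmax and the permutation p-value are unchanged.
// Validity: arc and complement each hold >= minw markers, and the flanking
// pieces left by a split are either empty or >= minw markers.
static double max_stat(const std::vector<double>& x, int minw,
                       int* bi, int* bj) {
  const int n = (int)x.size();
  std::vector<double> C(n + 1, 0.0);
  for (int k = 0; k < n; ++k) C[k + 1] = C[k] + x[k];
  const double tot = C[n];
  double best = -1.0;
  int besti = -1, bestj = -1;
  for (int l = minw; l <= n - minw; ++l) {
    const double invl = 1.0 / l, invr = 1.0 / (n - l);
    const double denom = std::sqrt(invl + invr);
    for (int i = 0; i + l <= n; ++i) {
      if (i != 0 && i < minw) continue;
      const int j = i + l;
      if (j != n && n - j < minw) continue;
      const double S = C[j] - C[i];
      const double t = std::fabs((S * invl - (tot - S) * invr) / denom);
      if (t > best) { best = t; besti = i; bestj = j; }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

// One CBS scan of a marker series: the best arc and its permutation p-value.
// Permutations stop early once significance at `alpha` has become impossible
// (the exceedance count already implies p > alpha); the reported p-value is
// then computed over the permutations actually drawn and is > alpha by
// construction, so accept/reject decisions are unaffected.
// [[Rcpp::export]]
List cbs_scan_cpp(NumericVector x, int min_markers, int n_perm, double alpha) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  int bi = -1, bj = -1;
  const double obs = max_stat(v, min_markers, &bi, &bj);
  if (obs < 0.0) {
    return List::create(_["i"] = 0, _["j"] = n, _["stat"] = NA_REAL,
                        _["p"] = 1.0, _["n_perm"] = 0);
  }
  const double limit = alpha * (n_perm + 1.0);
  int exceed = 0, done = 0;
  std::vector<double> perm(v);
  GetRNGstate();
  for (int b = 0; b < n_perm; ++b) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(perm[k], perm[idx]);
    }
    if (max_stat(perm, min_markers, nullptr, nullptr) >= obs) ++exceed;
    ++done;
    if (exceed + 1.0 > limit) break;
  }
  PutRNGstate();
  const double p = (exceed + 1.0) / (done + 1.0);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = obs,
                      _["p"] = p, _["n_perm"] = done);
}
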