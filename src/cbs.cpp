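#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// A candidate change is an arc (i, j] on the circularised segment, reported
// in linear coordinates as cut positions i and j (0-based, 0 <= i < j <= n).
// Accepting it cuts the linear segment into the non-empty pieces among
// [0,i), [i,j), [j,n).  With minimum segment width mw every non-empty piece
// must hold at least mw bins (the five-contiguous-bin transition rule when
// mw = 5).  An arc and its complement describe the same partition, so only
// canonical arcs with j < n are enumerated (the suffix arc (i, n] equals the
// prefix arc (0, i]); this keeps exact ties between the two encodings of one
// partition out of the scan.
//
// The statistic is the pooled-variance two-sample t comparing the arc mean
// with the complement mean; the scan maximises its square,
//   t^2 = d^2 * k * m * (n-2) / (ssw * n),
// where d is the mean difference, k/m the side sizes and ssw the pooled
// within-side sum of squares.  ssw == 0 with d != 0 gives +Inf (perfect
// separation); constant data gives NaN everywhere and is reported as "no
// split" (bstat = -1).  Ties keep the leftmost (i, j).
static void best_split_core(const double *x, int n, int mw,
                            const double *invk,
                            int &bi, int &bj, double &bstat) {
  bi = -1; bj = -1; bstat = -1.0;
  if (n < 3 || n < 2 * mw) return;
  std::vector<double> S(n + 1);
  double tot = 0.0, totq = 0.0;
  S[0] = 0.0;
  for (int t = 0; t < n; ++t) {
    tot += x[t];
    totq += x[t] * x[t];
    S[t + 1] = tot;
  }
  const double c = (double)(n - 2) / n;
  double best2 = -1.0;
  const int jhi = n - mw;
  for (int i = 0; i <= n - 2 * mw; ++i) {
    if (i > 0 && i < mw) { i = mw - 1; continue; }
    const double Si = S[i];
    for (int j = i + mw; j <= jhi; ++j) {
      const int k = j - i, m = n - k;
      const double sa = S[j] - Si;
      const double ma = sa * invk[k], mc = (tot - sa) * invk[m];
      const double d = ma - mc;
      const double ssw = totq - sa * ma - (tot - sa) * mc;
      const double t2 = d * d * k * m * c / ssw;
      if (t2 > best2) { best2 = t2; bi = i; bj = j; }
    }
  }
  if (bi >= 0) bstat = std::sqrt(best2);
}

static std::vector<double> inv_table(int n) {
  std::vector<double> invk(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) invk[k] = 1.0 / k;
  return invk;
}

// [[Rcpp::export]]
List cpp_best_split(NumericVector x, int min_width) {
  int bi, bj; double bstat;
  std::vector<double> invk = inv_table(x.size());
  best_split_core(x.begin(), x.size(), min_width, invk.data(), bi, bj, bstat);
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = bstat);
}

// Permutation test for the maximal split statistic.  Uses R's RNG so results
// are reproducible under set.seed().  Stops sequentially once the exceedance
// count reaches h = ceil(alpha * n_perm): the reported p = h/used is then
// >= alpha, so the accept/reject decision is identical to the full run.
// [[Rcpp::export]]
List cpp_segment_test(NumericVector x, int min_width, int n_perm, double alpha) {
  const int n = x.size();
  std::vector<double> invk = inv_table(n);
  int bi, bj; double bstat;
  best_split_core(x.begin(), n, min_width, invk.data(), bi, bj, bstat);
  if (bi < 0 || !(bstat > 0.0)) {
    return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = bstat,
                        _["p"] = 1.0, _["n_perm_used"] = 0);
  }
  std::vector<double> y(x.begin(), x.end());
  const int h = (int)std::ceil(alpha * n_perm);
  int exceed = 0, used = 0;
  for (int b = 0; b < n_perm; ++b) {
    for (int t = n - 1; t > 0; --t) {        // Fisher-Yates on R uniforms
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(y[t], y[u]);
    }
    int pi, pj; double pstat;
    best_split_core(y.data(), n, min_width, invk.data(), pi, pj, pstat);
    ++used;
    if (pstat >= bstat) ++exceed;
    if (exceed >= h) break;
  }
  const double p = (used < n_perm) ? (double)exceed / used
                                   : (double)exceed / n_perm;
  return List::create(_["i"] = bi, _["j"] = bj, _["stat"] = bstat,
                      _["p"] = p, _["n_perm_used"] = used);
}
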