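#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal circular-arc t statistic for a mean shift inside one segment.
// The arc is x[i..j-1] (0-based, half-open); its complement is the rest of
// the segment.  Because |T| for an arc equals |T| for its complement, the
// linear double scan covers every circular arc.  Both arc and complement
// must hold at least min_seg points.
static void max_arc_stat(const std::vector<double>& x, int min_seg,
                         double& tmax, int& bi, int& bj) {
  const int n = (int)x.size();
  tmax = -1.0; bi = 0; bj = n;
  if (min_seg < 1) min_seg = 1;
  if (n < 2 * min_seg) return;

  std::vector<double> S(n + 1, 0.0);
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { S[i + 1] = S[i] + x[i]; ss += x[i] * x[i]; }
  const double tot = S[n];
  const double var = (ss - tot * tot / n) / n;
  if (var <= 0.0 || !std::isfinite(var)) return;
  const double sd = std::sqrt(var);

  for (int k = min_seg; k <= n - min_seg; ++k) {
    // T = |mean(arc) - mean(rest)| / (sd * sqrt(1/k + 1/(n-k)))
    const double w = 1.0 / (sd * std::sqrt((double)n / ((double)k * (double)(n - k))));
    const double inv_k = 1.0 / k, inv_r = 1.0 / (n - k);
    for (int i = 0; i + k <= n; ++i) {
      const double sa = S[i + k] - S[i];
      const double t = std::fabs(sa * inv_k - (tot - sa) * inv_r) * w;
      if (t > tmax) { tmax = t; bi = i; bj = i + k; }
    }
  }
}

// One CBS scan of a segment: observed max arc statistic plus its permutation
// p-value.  Permutations use R's RNG (so set.seed() in R governs them) and
// terminate early once significance at level alpha is no longer reachable.
// Returned i/j are 1-based inclusive bounds of the best arc.
// [[Rcpp::export]]
List cbs_scan(NumericVector x, int min_seg, int n_perm, double alpha) {
  std::vector<double> v = as<std::vector<double> >(x);
  double tobs; int bi, bj;
  max_arc_stat(v, min_seg, tobs, bi, bj);
  if (tobs < 0.0)
    return List::create(_["t"] = NA_REAL, _["i"] = NA_INTEGER,
                        _["j"] = NA_INTEGER, _["p"] = 1.0, _["n_perm_used"] = 0);

  const int stop_at = (int)std::ceil(alpha * n_perm);
  int exceed = 0, done = 0;
  std::vector<double> p = v;
  for (int r = 0; r < n_perm; ++r) {
    for (int i = (int)p.size() - 1; i > 0; --i) {  // Fisher-Yates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    double t; int a, b;
    max_arc_stat(p, min_seg, t, a, b);
    ++done;
    if (t >= tobs) {
      ++exceed;
      if (exceed >= stop_at) break;  // p-value cannot drop below alpha
    }
  }
  const double pval = (exceed + 1.0) / (done + 1.0);
  return List::create(_["t"] = tobs, _["i"] = bi + 1, _["j"] = bj,
                      _["p"] = pval, _["n_perm_used"] = done);
}
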