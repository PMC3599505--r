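#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Per-segment Minkowski energy from prefix sums over observed values.
// Residual sums of squares computed as ss - s^2/l can go slightly negative
// (or spuriously positive) by cancellation; a relative guard zeroes them.
static inline double seg_delta(const std::vector<double> &sr,
                               const std::vector<double> &sr2,
                               const std::vector<int> &cr,
                               const std::vector<double> &sb,
                               const std::vector<double> &sb2,
                               const std::vector<int> &cb,
                               int j, int x, double p, double beta) {
  const double rel_tol = 1e-9;
  int lr = cr[x] - cr[j];
  int lb = cb[x] - cb[j];
  int tot = lr + lb;
  if (tot == 0) return 0.0;
  double rss_r = 0.0, rss_b = 0.0;
  if (lr > 0) {
    double s = sr[x] - sr[j], ss = sr2[x] - sr2[j];
    rss_r = ss - s * s / lr;
    if (rss_r <= rel_tol * std::abs(ss)) rss_r = 0.0;
  }
  if (lb > 0) {
    double s = sb[x] - sb[j], ss = sb2[x] - sb2[j];
    rss_b = ss - s * s / lb;
    if (rss_b <= rel_tol * std::abs(ss)) rss_b = 0.0;
  }
  double wr = (double)lr / tot, wb = (double)lb / tot;
  double inner = 0.0;
  if (rss_r > 0.0) inner += wr * std::pow(rss_r, p);
  if (rss_b > 0.0) inner += wb * beta * std::pow(rss_b, p);
  return inner > 0.0 ? std::pow(inner, 1.0 / p) : 0.0;
}

// Exact DP over segmentations: cost[s][x] = min cost of tiling [0, x) with
// s segments, each of length <= max_len.  Ties broken toward the smaller
// (leftmost) predecessor index, giving deterministic change-point vectors.
// [[Rcpp::export]]
List dp_segment_cpp(NumericVector lrr, NumericVector imbaf,
                    LogicalVector lrr_obs, LogicalVector imbaf_obs,
                    double p, double beta, int max_segments, int max_len) {
  int n = lrr.size();
  if (n < 1) stop("empty series");
  if (max_len < 1) stop("max_len must be >= 1");
  int S = max_segments;

  std::vector<double> sr(n + 1, 0.0), sr2(n + 1, 0.0), sb(n + 1, 0.0), sb2(n + 1, 0.0);
  std::vector<int> cr(n + 1, 0), cb(n + 1, 0);
  for (int k = 0; k < n; ++k) {
    sr[k + 1] = sr[k]; sr2[k + 1] = sr2[k]; cr[k + 1] = cr[k];
    sb[k + 1] = sb[k]; sb2[k + 1] = sb2[k]; cb[k + 1] = cb[k];
    if (lrr_obs[k]) { sr[k + 1] += lrr[k]; sr2[k + 1] += lrr[k] * lrr[k]; cr[k + 1] += 1; }
    if (imbaf_obs[k]) { sb[k + 1] += imbaf[k]; sb2[k + 1] += imbaf[k] * imbaf[k]; cb[k + 1] += 1; }
  }

  const double INF = std::numeric_limits<double>::infinity();
  int L = std::min(max_len, n);

  // Precompute delta(x - d, x) for d = 1..L when it fits in memory;
  // otherwise recompute on the fly inside the DP loops.
  bool cache = (double)n * L <= 3e7;
  std::vector<double> D;
  if (cache) {
    D.assign((size_t)n * L, 0.0);
    for (int x = 1; x <= n; ++x) {
      int dmax = std::min(L, x);
      for (int d = 1; d <= dmax; ++d)
        D[(size_t)(x - 1) * L + (d - 1)] =
          seg_delta(sr, sr2, cr, sb, sb2, cb, x - d, x, p, beta);
    }
  }

  std::vector<double> prev(n + 1, INF), cur(n + 1, INF);
  std::vector<int> bp((size_t)S * (n + 1), -1);
  NumericVector costs(S);
  List cps(S);

  for (int x = 1; x <= n; ++x) {
    if (x <= L) {
      prev[x] = cache ? D[(size_t)(x - 1) * L + (x - 1)]
                      : seg_delta(sr, sr2, cr, sb, sb2, cb, 0, x, p, beta);
      bp[(size_t)0 * (n + 1) + x] = 0;
    }
  }
  costs[0] = prev[n];

  for (int s = 2; s <= S; ++s) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int x = s; x <= n; ++x) {
      int jlo = std::max(s - 1, x - L);
      double best = INF; int bestj = -1;
      for (int j = jlo; j <= x - 1; ++j) {
        double g = prev[j];
        if (!std::isfinite(g)) continue;
        double d = cache ? D[(size_t)(x - 1) * L + (x - j - 1)]
                         : seg_delta(sr, sr2, cr, sb, sb2, cb, j, x, p, beta);
        double cand = g + d;
        if (cand < best) { best = cand; bestj = j; }
      }
      cur[x] = best;
      bp[(size_t)(s - 1) * (n + 1) + x] = bestj;
    }
    costs[s - 1] = cur[n];
    std::swap(prev, cur);
  }

  for (int s = 1; s <= S; ++s) {
    if (!std::isfinite(costs[s - 1])) { cps[s - 1] = R_NilValue; continue; }
    IntegerVector t(s + 1);
    t[s] = n;
    int x = n;
    for (int q = s; q >= 1; --q) {
      int j = bp[(size_t)(q - 1) * (n + 1) + x];
      t[q - 1] = j;
      x = j;
    }
    cps[s - 1] = t;
  }

  return List::create(_["costs"] = costs, _["changepoints"] = cps);
}
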