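#include <Rcpp.h>
using namespace Rcpp;

// Exact segmented least squares by dynamic programming.
//
// For each number of change points k = 0..K, finds the piecewise-constant
// model of y with k change points minimizing the residual sum of squares.
// O(K * n^2) with O(1) per-segment cost via cumulative sums; exact, no
// pruning, so the fit is deterministic and globally optimal for each k.
//
// Returns a list with:
//   rss          : numeric(K+1), optimal RSS for k = 0..K change points
//   changepoints : list of integer vectors; element k+1 holds the 1-based
//                  index of the last sample of each of the first k
//                  segments (empty for k = 0)
// [[Rcpp::export(name = ".segmentDP")]]
List segmentDP(NumericVector y, int K) {
  const int n = y.size();
  if (n < 1) stop("empty trace");
  if (K < 0) stop("K must be >= 0");
  if (K > n - 1) K = n - 1;

  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + y[i];
    cs2[i + 1] = cs2[i] + y[i] * y[i];
  }
  // cost of fitting one level to y[i..j] (0-based, inclusive)
  auto cost = [&](int i, int j) {
    double s = cs[j + 1] - cs[i];
    double s2 = cs2[j + 1] - cs2[i];
    double len = j - i + 1;
    double c = s2 - s * s / len;
    return c > 0.0 ? c : 0.0;
  };

  // dp[k][t]: best RSS for y[0..t] using k change points
  std::vector<std::vector<double>> dp(K + 1, std::vector<double>(n));
  std::vector<std::vector<int>> arg(K + 1, std::vector<int>(n, -1));
  for (int t = 0; t < n; ++t) dp[0][t] = cost(0, t);
  for (int k = 1; k <= K; ++k) {
    for (int t = 0; t < n; ++t) {
      double best = R_PosInf;
      int bestS = -1;
      // last segment is y[s+1..t]; need s >= k-1 so earlier segments fit
      for (int s = k - 1; s < t; ++s) {
        double v = dp[k - 1][s] + cost(s + 1, t);
        if (v < best) { best = v; bestS = s; }
      }
      dp[k][t] = best;
      arg[k][t] = bestS;
    }
  }

  NumericVector rss(K + 1);
  List cps(K + 1);
  for (int k = 0; k <= K; ++k) {
    rss[k] = dp[k][n - 1];
    IntegerVector cp(k);
    int t = n - 1;
    for (int kk = k; kk >= 1; --kk) {
      int s = arg[kk][t];
      cp[kk - 1] = s + 1;  // 1-based index of last sample of segment kk
      t = s;
    }
    cps[k] = cp;
  }
  return List::create(Named("rss") = rss, Named("changepoints") = cps);
}
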