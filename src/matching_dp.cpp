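#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact maximum-weight perfect matching on a dense graph by dynamic
// programming over vertex subsets. dp[mask] is the best total weight of a
// perfect matching on the vertex set `mask`; the lowest set bit is always
// matched first, so each even-popcount mask is solved once. O(2^n * n) time,
// O(2^n) memory; n is capped in the R wrapper (memory guard).
//
// Reconstruction pairs the lowest free vertex with the smallest partner that
// attains the optimum (tolerance 1e-9), giving the lexicographically
// smallest sorted pair list among maximum-weight matchings.
// [[Rcpp::export]]
IntegerMatrix mwpm_dp(NumericMatrix w) {
  const int n = w.nrow();
  if (n % 2 != 0) stop("vertex count must be even");
  if (n > 26) stop("subset DP limited to n <= 26 vertices");
  const size_t full = (size_t)1 << n;
  std::vector<double> dp(full, R_NegInf);
  dp[0] = 0.0;
  for (size_t mask = 1; mask < full; ++mask) {
    int i = __builtin_ctzll(mask);
    if (__builtin_popcountll(mask) % 2 != 0) continue;
    size_t rest = mask & ~((size_t)1 << i);
    double best = R_NegInf;
    size_t m = rest;
    while (m) {
      int j = __builtin_ctzll(m);
      m &= m - 1;
      double v = dp[rest & ~((size_t)1 << j)] + w(i, j);
      if (v > best) best = v;
    }
    dp[mask] = best;
  }
  IntegerMatrix out(n / 2, 2);
  size_t mask = full - 1;
  int row = 0;
  while (mask) {
    int i = __builtin_ctzll(mask);
    size_t rest = mask & ~((size_t)1 << i);
    double target = dp[mask];
    double tol = 1e-9 * (1.0 + std::fabs(target));
    int pick = -1;
    size_t m = rest;
    while (m) {
      int j = __builtin_ctzll(m);
      m &= m - 1;
      if (dp[rest & ~((size_t)1 << j)] + w(i, j) >= target - tol) { pick = j; break; }
    }
    if (pick < 0) stop("internal error: reconstruction failed");
    out(row, 0) = i + 1;
    out(row, 1) = pick + 1;
    ++row;
    mask = rest & ~((size_t)1 << pick);
  }
  return out;
}
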