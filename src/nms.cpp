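#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy hard-core selection: points are visited in the given order (the
// caller pre-sorts by priority) and kept iff their Euclidean distance to
// every previously kept point is >= min_dist. A spatial hash with cell side
// min_dist bounds the neighbourhood scan to the 3x3 adjacent cells.
// [[Rcpp::export]]
LogicalVector nms_keep(NumericVector x, NumericVector y, double min_dist) {
  int n = x.size();
  LogicalVector keep(n);
  if (min_dist <= 0) {
    for (int i = 0; i < n; ++i) keep[i] = true;
    return keep;
  }
  double d2 = min_dist * min_dist;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  const long long OFF = 1 << 20, SPAN = 1LL << 21;
  for (int i = 0; i < n; ++i) {
    long long cx = (long long)std::floor(x[i] / min_dist);
    long long cy = (long long)std::floor(y[i] / min_dist);
    bool ok = true;
    for (long long dx = -1; dx <= 1 && ok; ++dx) {
      for (long long dy = -1; dy <= 1 && ok; ++dy) {
        long long key = (cx + dx + OFF) * SPAN + (cy + dy + OFF);
        std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find(key);
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy < d2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      keep[i] = true;
      grid[(cx + OFF) * SPAN + (cy + OFF)].push_back(i);
    }
  }
  return keep;
}
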