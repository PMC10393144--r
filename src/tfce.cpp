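#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Threshold-free cluster enhancement over an arbitrary adjacency graph.
//
// values:    non-negative statistic map (one value per node); callers handle
//            signed maps by enhancing the positive and negated-negative
//            parts separately.
// neighbors: concatenated 0-based neighbor indices
// offsets:   length n+1; node i has neighbors in [offsets[i], offsets[i+1])
// E, H:      extent and height exponents
// dh:        threshold step; thresholds run h = dh, 2dh, ... up to max(values)
//
// For every threshold the suprathreshold subgraph is labeled by an iterative
// depth-first search and each suprathreshold node accumulates
// extent^E * h^H * dh for its cluster.
// [[Rcpp::export(name = ".tfce_graph")]]
NumericVector tfce_graph(NumericVector values, IntegerVector neighbors,
                         IntegerVector offsets, double E, double H,
                         double dh) {
  const int n = values.size();
  NumericVector out(n);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) vmax = std::max(vmax, values[i]);
  if (vmax <= 0.0 || dh <= 0.0) return out;

  std::vector<int> label(n), stack, members;
  stack.reserve(n);
  members.reserve(n);

  // thresholds h = k * dh (computed by multiplication so results are
  // reproducible against straightforward R re-implementations)
  const int nh = (int)std::floor(vmax / dh + 1e-9);
  for (int k = 1; k <= nh; ++k) {
    const double h = k * dh;
    std::fill(label.begin(), label.end(), 0);
    int cur = 0;
    const double hH = std::pow(h, H) * dh;
    for (int seed = 0; seed < n; ++seed) {
      if (values[seed] < h || label[seed] != 0) continue;
      ++cur;
      members.clear();
      stack.clear();
      stack.push_back(seed);
      label[seed] = cur;
      while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        members.push_back(v);
        for (int k = offsets[v]; k < offsets[v + 1]; ++k) {
          int w = neighbors[k];
          if (values[w] >= h && label[w] == 0) {
            label[w] = cur;
            stack.push_back(w);
          }
        }
      }
      const double add = std::pow((double)members.size(), E) * hH;
      for (size_t m = 0; m < members.size(); ++m) out[members[m]] += add;
    }
  }
  return out;
}
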