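#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling with 26-connectivity.
// mask is a logical vector in R array order (first index fastest),
// dims its 3D extents. Returns integer labels, 0 = background.
// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % d1);
      int j = (int)((v / d1) % d2);
      int k = (int)(v / ((R_xlen_t)d1 * d2));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= d3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= d2) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= d1) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            R_xlen_t w = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
            if (mask[w] && labels[w] == 0) {
              labels[w] = current;
              stack.push_back(w);
            }
          }
        }
      }
    }
  }
  return labels;
}
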