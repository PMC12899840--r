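#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a 0/1 integer matrix.
// Labels are assigned in raster-scan order (row by row, left to right) of
// each component's first-encountered pixel, so ids are deterministic.
// Background stays 0.
// [[Rcpp::export]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next_id = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next_id;
      lab(r, c) = next_id;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int cr = idx % nr, ccol = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = cr + dr, cc = ccol + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next_id;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
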