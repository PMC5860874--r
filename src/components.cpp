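#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a logical matrix by flood fill.
// Labels are assigned in column-major scan order starting at 1, so the
// component containing the first (lowest linear index) true pixel gets
// label 1 — a deterministic ordering the rest of the pipeline relies on
// for tie-breaking.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(c * nr + r);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = pr + dr, c2 = pc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(c2 * nr + r2);
            }
          }
        }
      }
    }
  }
  return lab;
}
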