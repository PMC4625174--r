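#include <Rcpp.h>
#include <vector>

// 8-connected component labeling of a logical matrix by breadth-first
// search in raster order (row-major over rows, then columns), so label k
// is the k-th component encountered scanning top-to-bottom then
// left-to-right: labels come out ordered by (top-most, left-most) first
// pixel, and are consecutive positive integers.
// [[Rcpp::export(name = ".labelComponents8")]]
Rcpp::IntegerMatrix labelComponents8(Rcpp::LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int cr = idx % H, cc = idx / H;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return lab;
}
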