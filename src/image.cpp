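#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 3x3 median filter with reflection padding at the borders.
// [[Rcpp::export(name = ".median_filter3_cpp")]]
NumericMatrix median_filter3_cpp(NumericMatrix x) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  double nb[9];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0) ii = -ii;            // reflect (a b c -> b | a b c)
          if (ii >= H) ii = 2 * H - 2 - ii;
          if (jj < 0) jj = -jj;
          if (jj >= W) jj = 2 * W - 2 - jj;
          nb[k++] = x(ii, jj);
        }
      }
      std::nth_element(nb, nb + 4, nb + 9);
      out(i, j) = nb[4];
    }
  }
  return out;
}

// 4-connected component labelling of a logical matrix; labels 1..K by
// scan order, 0 for background.
// [[Rcpp::export(name = ".label4_cpp")]]
IntegerMatrix label4_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * H);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % H, cj = idx / H;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int ni = ci + di[d], nj = cj + dj[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
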