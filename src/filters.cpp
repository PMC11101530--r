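#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// mirror index into [0, n): symmetric reflection including the edge sample
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Exact sliding-window median with symmetric (reflect) border padding.
// 'w' is the full window edge length and must be odd.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix x, int w) {
  const int nr = x.nrow(), nc = x.ncol(), h = w / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(static_cast<size_t>(w) * w);
  const size_t mid = (static_cast<size_t>(w) * w) / 2;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      size_t k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        const int jj = reflect_idx(j + dj, nc);
        for (int di = -h; di <= h; ++di) {
          buf[k++] = x(reflect_idx(i + di, nr), jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Label connected foreground components (4- or 8-connectivity) by
// iterative flood fill. Returns 0 for background, 1..k for components.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int q = 0; q < nnb; ++q) {
          const int ni = pi + di8[q], nj = pj + dj8[q];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}
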