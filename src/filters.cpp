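#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Symmetric (half-sample) reflection: -1 -> 0, n -> n-1.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Pixel-wise Shannon entropy (bits) of the 256-bin intensity histogram in a
// window x window neighbourhood, with reflective border padding. `img` must
// already be quantised to integers in [0, 255].
// [[Rcpp::export]]
NumericMatrix local_entropy_cpp(IntegerMatrix img, int window) {
  const int h = img.nrow(), w = img.ncol(), r = window / 2;
  const int n = window * window;
  NumericMatrix out(h, w);
  std::vector<int> hist(256);
  // log2 lookup for counts 1..n avoids n calls to log2 per pixel
  std::vector<double> plogp(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) {
    double p = static_cast<double>(k) / n;
    plogp[k] = -p * std::log2(p);
  }
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect_idx(j + dj, w);
        for (int di = -r; di <= r; ++di) {
          const int ii = reflect_idx(i + di, h);
          ++hist[img(ii, jj)];
        }
      }
      double H = 0.0;
      for (int b = 0; b < 256; ++b) H += plogp[hist[b]];
      out(i, j) = H;
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask; labels 1..n assigned in
// column-major first-encounter order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) && lab(i, j) == 0) {
        ++next;
        lab(i, j) = next;
        stack.push_back(i + j * h);
        while (!stack.empty()) {
          const int idx = stack.back();
          stack.pop_back();
          const int ci = idx % h, cj = idx / h;
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int ni = ci + di, nj = cj + dj;
              if (ni >= 0 && ni < h && nj >= 0 && nj < w &&
                  mask(ni, nj) && lab(ni, nj) == 0) {
                lab(ni, nj) = next;
                stack.push_back(ni + nj * h);
              }
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}
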