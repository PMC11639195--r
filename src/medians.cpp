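#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "mirror.h"

using namespace Rcpp;

static double median_of(std::vector<double> &buf) {
  const size_t n = buf.size();
  const size_t m = n / 2;
  std::nth_element(buf.begin(), buf.begin() + m, buf.end());
  double hi = buf[m];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(buf.begin(), buf.begin() + m);
  return 0.5 * (lo + hi);
}

// Spatial median filter with half-sample symmetric padding; size must be odd.
// [[Rcpp::export(name = ".cpp_median2d")]]
NumericMatrix cpp_median2d(NumericMatrix img, int size) {
  const int H = img.nrow(), W = img.ncol(), h = size / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)size * size);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        const int cj = mirror_index(j + dj, W);
        for (int di = -h; di <= h; ++di)
          buf.push_back(img(mirror_index(i + di, H), cj));
      }
      out(i, j) = median_of(buf);
    }
  }
  return out;
}

// Rolling temporal median over the frame axis of a pixels-by-frames stack.
// Centered window of `window` frames, truncated at the sequence edges
// (an even truncated window averages the two middle order statistics).
// [[Rcpp::export(name = ".cpp_temporal_median")]]
NumericMatrix cpp_temporal_median(NumericMatrix stack, int window) {
  const int P = stack.nrow(), F = stack.ncol(), h = window / 2;
  NumericMatrix out(P, F);
  std::vector<double> buf;
  for (int f = 0; f < F; ++f) {
    const int lo = std::max(0, f - h), hi = std::min(F - 1, f + h);
    buf.resize(hi - lo + 1);
    for (int p = 0; p < P; ++p) {
      for (int g = lo; g <= hi; ++g) buf[g - lo] = stack(p, g);
      out(p, f) = median_of(buf);
    }
  }
  return out;
}
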