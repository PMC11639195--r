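#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "mirror.h"

using namespace Rcpp;

// Bilateral filter: weighted mean over a square support with Gaussian
// geometric-closeness (sigma_s, pixel units) and intensity-similarity
// (sigma_r, count units) kernels, normalized by the total weight W.
// window must be odd; mirror padding at the borders.
// [[Rcpp::export(name = ".cpp_bilateral")]]
NumericMatrix cpp_bilateral(NumericMatrix img, double sigma_s, double sigma_r,
                            int window) {
  const int H = img.nrow(), W = img.ncol(), h = window / 2;
  const NumericMatrix P = pad_mirror(img, h);
  const double inv2s2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double inv2r2 = 1.0 / (2.0 * sigma_r * sigma_r);
  // spatial kernel is shift invariant: precompute
  std::vector<double> G((size_t)window * window);
  for (int di = -h; di <= h; ++di)
    for (int dj = -h; dj <= h; ++dj)
      G[(di + h) * window + (dj + h)] =
          std::exp(-(di * di + dj * dj) * inv2s2);
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double ip = img(i, j);
      double num = 0.0, Wn = 0.0;
      for (int dj = -h; dj <= h; ++dj) {
        for (int di = -h; di <= h; ++di) {
          const double iq = P(i + h + di, j + h + dj);
          const double dI = ip - iq;
          const double w =
              G[(di + h) * window + (dj + h)] * std::exp(-dI * dI * inv2r2);
          num += w * iq;
          Wn += w;
        }
      }
      out(i, j) = num / Wn;
    }
  }
  return out;
}
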