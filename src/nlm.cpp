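#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "mirror.h"

using namespace Rcpp;

// Brute-force non-local means: literal double loop over sites and window
// offsets. Patch similarity is the (optionally Gaussian-weighted) sum of
// squared differences over the patch; weights w = exp(-ssd / sigma^2),
// normalized by Z(s). Serves as the oracle for the fast path.
// hw/hp are window/patch half-sizes (effective supports 2*hw+1, 2*hp+1).
// [[Rcpp::export(name = ".cpp_nlm_brute")]]
NumericMatrix cpp_nlm_brute(NumericMatrix img, double sigma, int hw, int hp,
                            bool gauss_kernel, double gauss_sigma) {
  const int H = img.nrow(), W = img.ncol(), k = hw + hp;
  const NumericMatrix P = pad_mirror(img, k);
  const int ps = 2 * hp + 1;
  std::vector<double> G((size_t)ps * ps, 1.0);
  if (gauss_kernel) {
    for (int pi = -hp; pi <= hp; ++pi)
      for (int pj = -hp; pj <= hp; ++pj)
        G[(pi + hp) * ps + (pj + hp)] =
            std::exp(-(pi * pi + pj * pj) / (2.0 * gauss_sigma * gauss_sigma));
  }
  const double s2 = sigma * sigma;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const int a = i + k, b = j + k;
      double num = 0.0, Z = 0.0;
      for (int di = -hw; di <= hw; ++di) {
        for (int dj = -hw; dj <= hw; ++dj) {
          double ssd = 0.0;
          for (int pi = -hp; pi <= hp; ++pi)
            for (int pj = -hp; pj <= hp; ++pj) {
              const double d =
                  P(a + pi, b + pj) - P(a + di + pi, b + dj + pj);
              ssd += G[(pi + hp) * ps + (pj + hp)] * d * d;
            }
          const double w = std::exp(-ssd / s2);
          num += w * P(a + di, b + dj);
          Z += w;
        }
      }
      out(i, j) = num / Z;
    }
  }
  return out;
}

// Fast non-local means via per-shift integral images of squared differences.
// For each shift d the summed-square-difference plane S_d gives every site's
// patch distance in O(1); the shift's weight plane exp(-boxsum/sigma^2)
// multiplies the shifted image and accumulates into the weighted average.
// Identical in value to the brute-force path under the uniform patch kernel.
// [[Rcpp::export(name = ".cpp_nlm_fast")]]
NumericMatrix cpp_nlm_fast(NumericMatrix img, double sigma, int hw, int hp) {
  const int H = img.nrow(), W = img.ncol(), k = hw + hp;
  const NumericMatrix P = pad_mirror(img, k);
  const int PH = H + 2 * k, PW = W + 2 * k;
  const double s2 = sigma * sigma;
  NumericMatrix num(H, W), Z(H, W);
  // integral image S has one guard row/col of zeros
  std::vector<double> S((size_t)(PH + 1) * (PW + 1), 0.0);
  const int SW = PW + 1;
  for (int di = -hw; di <= hw; ++di) {
    for (int dj = -hw; dj <= hw; ++dj) {
      const int alo = std::max(0, -di), ahi = PH - 1 - std::max(0, di);
      const int blo = std::max(0, -dj), bhi = PW - 1 - std::max(0, dj);
      for (int a = 0; a < PH; ++a) {
        for (int b = 0; b < PW; ++b) {
          double d2 = 0.0;
          if (a >= alo && a <= ahi && b >= blo && b <= bhi) {
            const double d = P(a, b) - P(a + di, b + dj);
            d2 = d * d;
          }
          S[(a + 1) * SW + (b + 1)] =
              d2 + S[a * SW + (b + 1)] + S[(a + 1) * SW + b] - S[a * SW + b];
        }
      }
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          const int a = i + k, b = j + k;
          const double ssd = S[(a + hp + 1) * SW + (b + hp + 1)] -
                             S[(a - hp) * SW + (b + hp + 1)] -
                             S[(a + hp + 1) * SW + (b - hp)] +
                             S[(a - hp) * SW + (b - hp)];
          const double w = std::exp(-ssd / s2);
          num(i, j) += w * P(a + di, b + dj);
          Z(i, j) += w;
        }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) out(i, j) = num(i, j) / Z(i, j);
  return out;
}
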