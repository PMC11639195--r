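#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include "mirror.h"

using namespace Rcpp;

// 2D adaptive alpha-trimmed mean. Per pixel x:
//   M(x)   = 2*beta*lambda*Max / (2*lambda*Max + beta*p(x - delta)),
//            p(z) = max(z, 0), rounded to the nearest odd integer (ties
//            upward) and clipped to [3, beta];
//   alpha(x) = x / (lambda * Max), clipped to [0, 0.5];
// then the M x M neighborhood (mirror padded) is sorted, ceil(alpha*M^2)
// entries are zero-weighted at each end, and the survivors averaged. When
// trimming removes everything (alpha -> 0.5) the median element is used.
// A 1e-9 guard keeps ceil() from overshooting on exact-integer products.
// [[Rcpp::export(name = ".cpp_atm")]]
NumericMatrix cpp_atm(NumericMatrix img, int beta, double lambda,
                      double delta) {
  const int H = img.nrow(), W = img.ncol();
  double mx = 0.0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (img(i, j) > mx) mx = img(i, j);
  if (mx <= 0.0) return clone(img);

  const int hb = beta / 2;
  const NumericMatrix P = pad_mirror(img, hb);
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)beta * beta);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double x = img(i, j);
      const double pz = std::max(x - delta, 0.0);
      const double Mreal =
          (2.0 * beta * lambda * mx) / (2.0 * lambda * mx + beta * pz);
      int kk = (int)std::floor((Mreal - 1.0) / 2.0 + 0.5 + 1e-12);
      int m = 2 * kk + 1;
      if (m < 3) m = 3;
      if (m > beta) m = beta;
      double alpha = x / (lambda * mx);
      if (alpha < 0.0) alpha = 0.0;
      if (alpha > 0.5) alpha = 0.5;
      const int m2 = m * m, h = m / 2;
      const int t = (int)std::ceil(alpha * m2 - 1e-9);
      buf.clear();
      for (int dj = -h; dj <= h; ++dj)
        for (int di = -h; di <= h; ++di)
          buf.push_back(P(i + hb + di, j + hb + dj));
      std::sort(buf.begin(), buf.end());
      if (m2 - 2 * t <= 0) {
        out(i, j) = buf[(m2 - 1) / 2];
      } else {
        double s = 0.0;
        for (int q = t; q < m2 - t; ++q) s += buf[q];
        out(i, j) = s / (m2 - 2 * t);
      }
    }
  }
  return out;
}
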