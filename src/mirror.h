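#ifndef CHERENKOV_MIRROR_H
#define CHERENKOV_MIRROR_H

#include <Rcpp.h>

// Half-sample symmetric reflection of index i into [0, n-1]:
// -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2. This is the boundary rule used by
// every windowed filter in the package and mirrored by the R-side oracles.
static inline int mirror_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static inline Rcpp::NumericMatrix pad_mirror(const Rcpp::NumericMatrix &img,
                                             int k) {
  const int H = img.nrow(), W = img.ncol();
  Rcpp::NumericMatrix out(H + 2 * k, W + 2 * k);
  for (int i = 0; i < H + 2 * k; ++i) {
    const int si = mirror_index(i - k, H);
    for (int j = 0; j < W + 2 * k; ++j)
      out(i, j) = img(si, mirror_index(j - k, W));
  }
  return out;
}

#endif
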