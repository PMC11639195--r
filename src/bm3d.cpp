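#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Two-stage BM3D collaborative filter under a white-Gaussian noise PSD.
// Transforms: 2D orthonormal DCT on blocks, 1D orthonormal Haar across the
// matched group (group size truncated to a power of two). For orthonormal
// transforms the white-noise coefficient variance collapses to sigma^2, so
// the hard threshold is lambda_thr * sigma and the Wiener gains are
// Y^2 / (Y^2 + mu^2 sigma^2) with Y the basic-estimate coefficients.
// Aggregation weights: 1/(sigma^2 * N_retained) (stage 1) and
// 1/(sigma^2 * sum g^2) (stage 2).

static void dct_matrix(int n, std::vector<double> &D) {
  D.assign((size_t)n * n, 0.0);
  for (int k = 0; k < n; ++k) {
    const double a = std::sqrt((k == 0 ? 1.0 : 2.0) / n);
    for (int j = 0; j < n; ++j)
      D[k * n + j] = a * std::cos(M_PI * (2 * j + 1) * k / (2.0 * n));
  }
}

// out = D * Z * D^T  (forward) or D^T * Z * D (inverse), n x n blocks
static void dct2_apply(const double *z, const std::vector<double> &D, int n,
                       bool inverse, double *out, double *tmp) {
  // tmp = A * Z where A = D (fwd) or D^T (inv)
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) {
      double s = 0.0;
      for (int q = 0; q < n; ++q) {
        const double a = inverse ? D[q * n + r] : D[r * n + q];
        s += a * z[q * n + c];
      }
      tmp[r * n + c] = s;
    }
  // out = tmp * A^T
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) {
      double s = 0.0;
      for (int q = 0; q < n; ++q) {
        const double a = inverse ? D[q * n + c] : D[c * n + q];
        s += tmp[r * n + q] * a;
      }
      out[r * n + c] = s;
    }
}

static void haar_fwd(double *v, int m) {
  if (m < 2) return;
  std::vector<double> tmp(m);
  for (int len = m; len > 1; len /= 2) {
    for (int i = 0; i < len / 2; ++i) {
      tmp[i] = (v[2 * i] + v[2 * i + 1]) * M_SQRT1_2;
      tmp[len / 2 + i] = (v[2 * i] - v[2 * i + 1]) * M_SQRT1_2;
    }
    std::copy(tmp.begin(), tmp.begin() + len, v);
  }
}

static void haar_inv(double *v, int m) {
  if (m < 2) return;
  std::vector<double> tmp(m);
  for (int len = 2; len <= m; len *= 2) {
    for (int i = 0; i < len / 2; ++i) {
      tmp[2 * i] = (v[i] + v[len / 2 + i]) * M_SQRT1_2;
      tmp[2 * i + 1] = (v[i] - v[len / 2 + i]) * M_SQRT1_2;
    }
    std::copy(tmp.begin(), tmp.begin() + len, v);
  }
}

// exported for the small-instance transform oracles in the test suite
// [[Rcpp::export(name = ".cpp_dct2")]]
NumericMatrix cpp_dct2(NumericMatrix block, bool inverse) {
  const int n = block.nrow();
  if (block.ncol() != n) stop("block must be square");
  std::vector<double> D;
  dct_matrix(n, D);
  std::vector<double> z((size_t)n * n), out((size_t)n * n),
      tmp((size_t)n * n);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) z[r * n + c] = block(r, c);
  dct2_apply(z.data(), D, n, inverse, out.data(), tmp.data());
  NumericMatrix res(n, n);
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) res(r, c) = out[r * n + c];
  return res;
}

// [[Rcpp::export(name = ".cpp_haar1d")]]
NumericVector cpp_haar1d(NumericVector v, bool inverse) {
  const int m = v.size();
  if (m & (m - 1)) stop("length must be a power of two");
  NumericVector out = clone(v);
  if (inverse)
    haar_inv(out.begin(), m);
  else
    haar_fwd(out.begin(), m);
  return out;
}

struct Cand {
  double dist;
  int i, j;
};

static inline bool cand_less(const Cand &x, const Cand &y) {
  return x.dist < y.dist ||
         (x.dist == y.dist && (x.i < y.i || (x.i == y.i && x.j < y.j)));
}

static std::vector<int> ref_coords(int extent, int B, int step) {
  std::vector<int> v;
  for (int p = 0; p + B <= extent; p += step) v.push_back(p);
  if (v.empty() || v.back() != extent - B) v.push_back(extent - B);
  return v;
}

// One BM3D stage. match_img drives block matching (noisy image in stage 1,
// basic estimate in stage 2); `pilot` supplies the Wiener-gain coefficients
// (ignored when wiener = false). Returns the aggregated estimate.
// [[Rcpp::export(name = ".cpp_bm3d_stage")]]
NumericMatrix cpp_bm3d_stage(NumericMatrix noisy, NumericMatrix match_img,
                             NumericMatrix pilot, double sigma, double gamma,
                             int B, int max_group, double lambda_thr,
                             double mu, int search_win, int step,
                             bool wiener) {
  const int H = noisy.nrow(), W = noisy.ncol(), N = B * B;
  const int reach = (search_win - B) / 2;
  std::vector<double> D;
  dct_matrix(B, D);
  NumericMatrix num(H, W), wt(H, W);
  const std::vector<int> ris = ref_coords(H, B, step);
  const std::vector<int> rjs = ref_coords(W, B, step);
  std::vector<Cand> cands;
  std::vector<double> grp, grpp, tmp((size_t)N), blk((size_t)N);
  const double bias = 2.0 * gamma * N * sigma * sigma;

  for (size_t a = 0; a < ris.size(); ++a) {
    for (size_t b = 0; b < rjs.size(); ++b) {
      const int ri = ris[a], rj = rjs[b];
      const int ilo = std::max(0, ri - reach), ihi = std::min(H - B, ri + reach);
      const int jlo = std::max(0, rj - reach), jhi = std::min(W - B, rj + reach);
      const int ncand = (ihi - ilo + 1) * (jhi - jlo + 1);
      // cache the reference block (contiguous, column-major)
      for (int c = 0; c < B; ++c)
        for (int r = 0; r < B; ++r)
          blk[c * B + r] = match_img(ri + r, rj + c);
      // keep the best max_group candidates; once full, candidates whose
      // partial SSD already exceeds the current worst are cut short
      // (result identical to a full sort under the same tie-break)
      cands.clear();
      double worst = R_PosInf;  // worst dist in the current best set
      for (int ci = ilo; ci <= ihi; ++ci) {
        for (int cj = jlo; cj <= jhi; ++cj) {
          const bool full = (int)cands.size() >= max_group;
          const double cut = full ? worst + bias : R_PosInf;
          double ssd = 0.0;
          for (int c = 0; c < B; ++c) {
            const double *mc = &match_img(ci, cj + c);
            const double *rc = &blk[c * B];
            for (int r = 0; r < B; ++r) {
              const double d = rc[r] - mc[r];
              ssd += d * d;
            }
            if (ssd > cut) break;
          }
          if (ssd > cut) continue;
          const Cand cnd{ssd - bias, ci, cj};
          if (!full) {
            cands.push_back(cnd);
          } else {
            // replace the worst member if the candidate beats it
            // (scan order gives earlier coordinates the tie win)
            Cand *wm = &cands[0];
            for (Cand &q : cands)
              if (cand_less(*wm, q)) wm = &q;
            if (cand_less(cnd, *wm)) *wm = cnd;
          }
          if ((int)cands.size() >= max_group) {
            worst = cands[0].dist;
            for (const Cand &q : cands)
              if (q.dist > worst) worst = q.dist;
          }
        }
      }
      (void)ncand;
      int M = (int)cands.size();
      while (M & (M - 1)) --M;  // power of two
      std::sort(cands.begin(), cands.end(), cand_less);
      // 2D transform each matched block
      grp.assign((size_t)M * N, 0.0);
      if (wiener) grpp.assign((size_t)M * N, 0.0);
      for (int m = 0; m < M; ++m) {
        for (int c = 0; c < B; ++c)
          for (int r = 0; r < B; ++r)
            blk[r * B + c] = noisy(cands[m].i + r, cands[m].j + c);
        dct2_apply(blk.data(), D, B, false, grp.data() + (size_t)m * N,
                   tmp.data());
        if (wiener) {
          for (int c = 0; c < B; ++c)
            for (int r = 0; r < B; ++r)
              blk[r * B + c] = pilot(cands[m].i + r, cands[m].j + c);
          dct2_apply(blk.data(), D, B, false, grpp.data() + (size_t)m * N,
                     tmp.data());
        }
      }
      // 1D Haar across the group per coefficient, shrink, invert
      std::vector<double> col(M), colp(M);
      double weight;
      int nret = 0;
      double sg2 = 0.0;
      for (int i = 0; i < N; ++i) {
        for (int m = 0; m < M; ++m) col[m] = grp[(size_t)m * N + i];
        haar_fwd(col.data(), M);
        if (!wiener) {
          const double thr = lambda_thr * sigma;
          for (int m = 0; m < M; ++m) {
            if (std::fabs(col[m]) >= thr)
              ++nret;
            else
              col[m] = 0.0;
          }
        } else {
          for (int m = 0; m < M; ++m) colp[m] = grpp[(size_t)m * N + i];
          haar_fwd(colp.data(), M);
          for (int m = 0; m < M; ++m) {
            const double Y = colp[m];
            const double g = (Y * Y) / (Y * Y + mu * mu * sigma * sigma);
            col[m] *= g;
            sg2 += g * g;
          }
        }
        haar_inv(col.data(), M);
        for (int m = 0; m < M; ++m) grp[(size_t)m * N + i] = col[m];
      }
      if (!wiener)
        weight = nret >= 1 ? 1.0 / (sigma * sigma * nret) : 1.0;
      else
        weight = sg2 > 0 ? 1.0 / (sigma * sigma * sg2) : 1.0;
      // inverse 2D transform and aggregation
      for (int m = 0; m < M; ++m) {
        dct2_apply(grp.data() + (size_t)m * N, D, B, true, blk.data(),
                   tmp.data());
        for (int c = 0; c < B; ++c)
          for (int r = 0; r < B; ++r) {
            num(cands[m].i + r, cands[m].j + c) += weight * blk[r * B + c];
            wt(cands[m].i + r, cands[m].j + c) += weight;
          }
      }
    }
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = wt(i, j) > 0 ? num(i, j) / wt(i, j) : noisy(i, j);
  return out;
}
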