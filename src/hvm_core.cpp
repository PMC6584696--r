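// Low-level raster kernels shared by the stabilization and line-detection
// stages: separable convolution with replicated borders, bilinear sampling,
// similarity warping with validity marking, and sparse pyramidal
// Lucas-Kanade feature tracking.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable convolution, replicate border. Kernels are odd-length and applied
// as correlation along rows (kr, i.e. vertical) and columns (kc, horizontal);
// symmetric/antisymmetric Gaussian-derivative kernels make the distinction
// from convolution irrelevant up to sign, which callers account for.
// [[Rcpp::export]]
NumericMatrix cpp_sep_filter(const NumericMatrix& img,
                             const NumericVector& kr,
                             const NumericVector& kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hr = (kr.size() - 1) / 2, hc = (kc.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // vertical pass (along rows within each column)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -hr; k <= hr; ++k) {
        int ii = i + k;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += kr[k + hr] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // horizontal pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -hc; k <= hc; ++k) {
        int jj = j + k;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        acc += kc[k + hc] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

static inline double bilinear_at(const NumericMatrix& img, double r, double c,
                                 bool* ok = nullptr) {
  const int nr = img.nrow(), nc = img.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) {
    if (ok) *ok = false;
    return NA_REAL;
  }
  if (ok) *ok = true;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 >= nr - 1) r0 = nr - 2;
  if (c0 >= nc - 1) c0 = nc - 2;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * (1 - fc) * img(r0, c0) + (1 - fr) * fc * img(r0, c0 + 1) +
         fr * (1 - fc) * img(r0 + 1, c0) + fr * fc * img(r0 + 1, c0 + 1);
}

// Bilinear sampling at subpixel (row, col) positions, 0-based. Positions
// outside the raster return NA.
// [[Rcpp::export]]
NumericVector cpp_bilinear(const NumericMatrix& img,
                           const NumericVector& row,
                           const NumericVector& col) {
  const int n = row.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = bilinear_at(img, row[i], col[i]);
  return out;
}

// Inverse-mapped similarity warp: out(r, c) = img(M * (r, c)) where M is the
// 2x3 matrix mapping output (row, col, 1) to input (row, col). Out-of-frame
// samples become NA so the caller can compute the common valid region.
// [[Rcpp::export]]
NumericMatrix cpp_warp_similarity(const NumericMatrix& img,
                                  const NumericMatrix& M) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double a = M(0, 0), b = M(0, 1), tx = M(0, 2);
  const double c = M(1, 0), d = M(1, 1), ty = M(1, 2);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double sr = a * i + b * j + tx;
      double sc = c * i + d * j + ty;
      out(i, j) = bilinear_at(img, sr, sc);
    }
  }
  return out;
}

// 2x block-mean downsampling used for image pyramids and the large-vessel
// detection pass; odd trailing rows/cols are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_downsample2(const NumericMatrix& img) {
  const int nr = img.nrow() / 2, nc = img.ncol() / 2;
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = 0.25 * (img(2 * i, 2 * j) + img(2 * i + 1, 2 * j) +
                          img(2 * i, 2 * j + 1) + img(2 * i + 1, 2 * j + 1));
  return out;
}

// Minimum eigenvalue of the gradient structure tensor (Shi-Tomasi corner
// response), gradients by central differences, tensor box-summed over a
// (2*half+1)^2 window.
// [[Rcpp::export]]
NumericMatrix cpp_min_eig(const NumericMatrix& img, int half) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix gr(nr, nc), gc(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int im = i > 0 ? i - 1 : 0, ip = i < nr - 1 ? i + 1 : nr - 1;
      int jm = j > 0 ? j - 1 : 0, jp = j < nc - 1 ? j + 1 : nc - 1;
      gr(i, j) = 0.5 * (img(ip, j) - img(im, j));
      gc(i, j) = 0.5 * (img(i, jp) - img(i, jm));
    }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double a = 0, b = 0, c = 0;
      for (int dj = -half; dj <= half; ++dj)
        for (int di = -half; di <= half; ++di) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          double x = gr(ii, jj), y = gc(ii, jj);
          a += x * x; b += x * y; c += y * y;
        }
      double tr = a + c, det = std::sqrt((a - c) * (a - c) + 4 * b * b);
      out(i, j) = 0.5 * (tr - det);
    }
  return out;
}

struct Pyramid {
  std::vector<NumericMatrix> lev;
};

static Pyramid build_pyramid(const NumericMatrix& img, int levels) {
  Pyramid p;
  p.lev.push_back(img);
  for (int l = 1; l < levels; ++l) {
    const NumericMatrix& prev = p.lev.back();
    if (prev.nrow() < 16 || prev.ncol() < 16) break;
    p.lev.push_back(cpp_downsample2(prev));
  }
  return p;
}

// Sparse iterative Lucas-Kanade with pyramids. Tracks 0-based (row, col)
// points from `prev` into `next`; returns matrix [row, col, status].
// [[Rcpp::export]]
NumericMatrix cpp_lk_track(const NumericMatrix& prev,
                           const NumericMatrix& nxt,
                           const NumericVector& row,
                           const NumericVector& col,
                           int win_half, int levels, int max_iter,
                           double eps) {
  Pyramid pp = build_pyramid(prev, levels);
  Pyramid pn = build_pyramid(nxt, levels);
  const int L = (int)pp.lev.size();
  const int n = row.size();
  NumericMatrix out(n, 3);
  const int W = 2 * win_half + 1;
  std::vector<double> Ix(W * W), Iy(W * W), T(W * W);

  for (int f = 0; f < n; ++f) {
    double gr = 0.0, gc = 0.0;  // displacement guess at current level
    bool ok = true;
    for (int l = L - 1; l >= 0; --l) {
      const NumericMatrix& I0 = pp.lev[l];
      const NumericMatrix& I1 = pn.lev[l];
      const double scale = std::pow(2.0, l);
      const double pr = row[f] / scale, pc = col[f] / scale;
      // template and its gradients around (pr, pc) in I0
      double a11 = 0, a12 = 0, a22 = 0;
      bool valid = true;
      int idx = 0;
      for (int dj = -win_half; dj <= win_half && valid; ++dj)
        for (int di = -win_half; di <= win_half; ++di, ++idx) {
          double r = pr + di, c = pc + dj;
          bool s;
          double v = bilinear_at(I0, r, c, &s);
          double vr1 = bilinear_at(I0, r + 0.5, c, &s);
          double vr0 = bilinear_at(I0, r - 0.5, c, &s);
          double vc1 = bilinear_at(I0, r, c + 0.5, &s);
          double vc0 = bilinear_at(I0, r, c - 0.5, &s);
          if (ISNAN(v) || ISNAN(vr1) || ISNAN(vr0) || ISNAN(vc1) ||
              ISNAN(vc0)) {
            valid = false;
            break;
          }
          T[idx] = v;
          Ix[idx] = vr1 - vr0;
          Iy[idx] = vc1 - vc0;
          a11 += Ix[idx] * Ix[idx];
          a12 += Ix[idx] * Iy[idx];
          a22 += Iy[idx] * Iy[idx];
        }
      double det = a11 * a22 - a12 * a12;
      if (!valid || det < 1e-10) {
        if (l == 0) ok = false;
        gr *= 2.0; gc *= 2.0;
        continue;
      }
      for (int it = 0; it < max_iter; ++it) {
        double b1 = 0, b2 = 0;
        bool sane = true;
        idx = 0;
        for (int dj = -win_half; dj <= win_half && sane; ++dj)
          for (int di = -win_half; di <= win_half; ++di, ++idx) {
            bool s;
            double v = bilinear_at(I1, pr + gr + di, pc + gc + dj, &s);
            if (!s) { sane = false; break; }
            double e = v - T[idx];
            b1 += e * Ix[idx];
            b2 += e * Iy[idx];
          }
        if (!sane) { ok = (l != 0) ? ok : false; break; }
        double dr = -(a22 * b1 - a12 * b2) / det;
        double dc = -(a11 * b2 - a12 * b1) / det;
        gr += dr; gc += dc;
        if (std::sqrt(dr * dr + dc * dc) < eps) break;
      }
      if (l > 0) { gr *= 2.0; gc *= 2.0; }
    }
    double nr1 = row[f] + gr, nc1 = col[f] + gc;
    if (nr1 < 0 || nc1 < 0 || nr1 > nxt.nrow() - 1.0 ||
        nc1 > nxt.ncol() - 1.0)
      ok = false;
    out(f, 0) = nr1;
    out(f, 1) = nc1;
    out(f, 2) = ok ? 1.0 : 0.0;
  }
  return out;
}
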