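#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Global pixel frame: x = column, y = row, 0-based, pixel centers at
// integer coordinates. All routines below use this convention.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Keys cubic-convolution kernel with free parameter a (a = -0.5 is the
// Catmull-Rom member: C1, linear-precision, sharp high-frequency response).
static inline double cubic_w(double s, double a) {
  s = std::fabs(s);
  if (s < 1.0) return ((a + 2.0) * s - (a + 3.0)) * s * s + 1.0;
  if (s < 2.0) return ((a * s - 5.0 * a) * s + 8.0 * a) * s - 4.0 * a;
  return 0.0;
}

// Separable cubic-convolution sampling at arbitrary subpixel points,
// edges handled by clamping (sample replication).
// [[Rcpp::export]]
NumericVector cpp_interp_cubic(const NumericMatrix& img,
                               const NumericVector& x,
                               const NumericVector& y,
                               double a) {
  const int nr = img.nrow(), nc = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    const int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi);
    double acc = 0.0;
    for (int m = -1; m <= 2; ++m) {
      const double wy = cubic_w(yi - (y0 + m), a);
      if (wy == 0.0) continue;
      const int r = clampi(y0 + m, 0, nr - 1);
      for (int k = -1; k <= 2; ++k) {
        const double wx = cubic_w(xi - (x0 + k), a);
        if (wx == 0.0) continue;
        const int c = clampi(x0 + k, 0, nc - 1);
        acc += wy * wx * img(r, c);
      }
    }
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_interp_bilinear(const NumericMatrix& img,
                                  const NumericVector& x,
                                  const NumericVector& y) {
  const int nr = img.nrow(), nc = img.ncol(), n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i];
    if (xi < 0) xi = 0; if (xi > nc - 1) xi = nc - 1;
    if (yi < 0) yi = 0; if (yi > nr - 1) yi = nr - 1;
    const int x0 = clampi((int)std::floor(xi), 0, nc - 1);
    const int y0 = clampi((int)std::floor(yi), 0, nr - 1);
    const int x1 = clampi(x0 + 1, 0, nc - 1);
    const int y1 = clampi(y0 + 1, 0, nr - 1);
    const double fx = xi - x0, fy = yi - y0;
    out[i] = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
             fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& img, int nr_out, int nc_out) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr_out, nc_out);
  const double sy = nr_out > 1 ? (double)(nr - 1) / (nr_out - 1) : 0.0;
  const double sx = nc_out > 1 ? (double)(nc - 1) / (nc_out - 1) : 0.0;
  for (int c = 0; c < nc_out; ++c) {
    const double xi = c * sx;
    const int x0 = clampi((int)std::floor(xi), 0, nc - 1);
    const int x1 = clampi(x0 + 1, 0, nc - 1);
    const double fx = xi - x0;
    for (int r = 0; r < nr_out; ++r) {
      const double yi = r * sy;
      const int y0 = clampi((int)std::floor(yi), 0, nr - 1);
      const int y1 = clampi(y0 + 1, 0, nr - 1);
      const double fy = yi - y0;
      out(r, c) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
                  fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
    }
  }
  return out;
}

// Selective Gaussian blur: each pixel becomes the Gaussian-weighted mean
// of itself and those neighbours whose intensity difference from it stays
// below a per-pixel tolerance; a pixel with no qualifying neighbour is
// left untouched.
// [[Rcpp::export]]
NumericMatrix cpp_selective_gaussian(const NumericMatrix& img,
                                     const NumericMatrix& tol,
                                     double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> g(2 * rad + 1);
  for (int d = -rad; d <= rad; ++d)
    g[d + rad] = std::exp(-0.5 * d * d / (sigma * sigma));
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double v0 = img(r, c), t = tol(r, c);
      double sw = 0.0, sv = 0.0;
      bool any = false;
      for (int dc = -rad; dc <= rad; ++dc) {
        const int cc = c + dc;
        if (cc < 0 || cc >= nc) continue;
        for (int dr = -rad; dr <= rad; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= nr) continue;
          if (dr == 0 && dc == 0) continue;
          const double v = img(rr, cc);
          if (std::fabs(v - v0) < t) {
            const double w = g[dr + rad] * g[dc + rad];
            sw += w; sv += w * v;
            any = true;
          }
        }
      }
      if (!any) { out(r, c) = v0; continue; }
      sw += 1.0; sv += v0;   // centre always participates once a neighbour does
      out(r, c) = sv / sw;
    }
  }
  return out;
}

// Harmonic (Laplace) inpainting by Gauss-Seidel relaxation on the masked
// set, Dirichlet boundary taken from unmasked pixels.
// [[Rcpp::export]]
NumericMatrix cpp_inpaint(const NumericMatrix& img,
                          const LogicalMatrix& mask,
                          double tol, int max_iter) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(clone(img));
  std::vector<int> mr, mc;
  double init = 0.0; int nfree = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c)) { mr.push_back(r); mc.push_back(c); }
      else { init += img(r, c); ++nfree; }
    }
  if (mr.empty()) return out;
  init = nfree > 0 ? init / nfree : 0.0;
  for (size_t i = 0; i < mr.size(); ++i) out(mr[i], mc[i]) = init;
  // SOR with the classical optimal factor for a Laplace problem whose
  // effective grid dimension is sqrt(|mask|)
  const double neff = std::max(2.0, std::sqrt((double)mr.size()));
  const double omega = 2.0 / (1.0 + std::sin(M_PI / (neff + 1.0)));
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (size_t i = 0; i < mr.size(); ++i) {
      const int r = mr[i], c = mc[i];
      double s = 0.0; int k = 0;
      if (r > 0)      { s += out(r - 1, c); ++k; }
      if (r < nr - 1) { s += out(r + 1, c); ++k; }
      if (c > 0)      { s += out(r, c - 1); ++k; }
      if (c < nc - 1) { s += out(r, c + 1); ++k; }
      const double v = out(r, c) + omega * (s / k - out(r, c));
      delta = std::max(delta, std::fabs(v - out(r, c)));
      out(r, c) = v;
    }
    if (delta < tol) break;
  }
  return out;
}

// ---- Haar cascade machinery -------------------------------------------

// padded integral images (nr+1 x nc+1)
static void integrals(const NumericMatrix& img,
                      std::vector<double>& ii, std::vector<double>& ii2,
                      int nr, int nc) {
  const int w = nc + 1;
  ii.assign((nr + 1) * w, 0.0);
  ii2.assign((nr + 1) * w, 0.0);
  for (int r = 0; r < nr; ++r) {
    double rs = 0.0, rs2 = 0.0;
    for (int c = 0; c < nc; ++c) {
      const double v = img(r, c);
      rs += v; rs2 += v * v;
      ii[(r + 1) * w + (c + 1)] = ii[r * w + (c + 1)] + rs;
      ii2[(r + 1) * w + (c + 1)] = ii2[r * w + (c + 1)] + rs2;
    }
  }
}

static inline double rsum(const std::vector<double>& ii, int w,
                          int r0, int c0, int rh, int cw) {
  // sum of rows [r0, r0+rh), cols [c0, c0+cw)
  return ii[(r0 + rh) * w + (c0 + cw)] - ii[r0 * w + (c0 + cw)]
       - ii[(r0 + rh) * w + c0] + ii[r0 * w + c0];
}

// Haar feature kinds (zero-sum weighted rectangle combinations):
// 0 edge_h  : top half (+1), bottom half (-1)          [h even]
// 1 edge_v  : left half (+1), right half (-1)          [w even]
// 2 line_h  : whole (+1), middle horizontal third (-3) [h %% 3 == 0]
// 3 line_v  : whole (+1), middle vertical third (-3)   [w %% 3 == 0]
// 4 center_surround: whole (+1), centred half-size core (-4) [w,h %% 4 == 0]
// 5 tilted_edge: diagonally offset half-size pair (+1 / -1)  [w,h even]
static inline double feat_raw(const std::vector<double>& ii, int w,
                              int kind, int fy, int fx, int fw, int fh) {
  switch (kind) {
  case 0: return rsum(ii, w, fy, fx, fh / 2, fw) - rsum(ii, w, fy + fh / 2, fx, fh / 2, fw);
  case 1: return rsum(ii, w, fy, fx, fh, fw / 2) - rsum(ii, w, fy, fx + fw / 2, fh, fw / 2);
  case 2: return rsum(ii, w, fy, fx, fh, fw) - 3.0 * rsum(ii, w, fy + fh / 3, fx, fh / 3, fw);
  case 3: return rsum(ii, w, fy, fx, fh, fw) - 3.0 * rsum(ii, w, fy, fx + fw / 3, fh, fw / 3);
  case 4: return rsum(ii, w, fy, fx, fh, fw) - 4.0 * rsum(ii, w, fy + fh / 4, fx + fw / 4, fh / 2, fw / 2);
  case 5: return rsum(ii, w, fy, fx, fh / 2, fw / 2) - rsum(ii, w, fy + fh / 2, fx + fw / 2, fh / 2, fw / 2);
  }
  return 0.0;
}

// Responses of every feature on every fixed-size sample window, with
// variance normalization (response / window sd; zero-variance -> 0).
// samples: (win_h*win_w) x n, each column one window, column-major layout.
// feats: F x 5 integer matrix (kind, x, y, w, h), window-relative.
// [[Rcpp::export]]
NumericMatrix cpp_feature_responses(const NumericMatrix& samples,
                                    int win_h, int win_w,
                                    const IntegerMatrix& feats) {
  const int n = samples.ncol(), F = feats.nrow();
  NumericMatrix out(n, F);
  const int w = win_w + 1;
  const double area = (double)win_h * win_w;
  std::vector<double> ii, ii2;
  NumericMatrix tmp(win_h, win_w);
  for (int s = 0; s < n; ++s) {
    for (int c = 0; c < win_w; ++c)
      for (int r = 0; r < win_h; ++r)
        tmp(r, c) = samples(c * win_h + r, s);
    integrals(tmp, ii, ii2, win_h, win_w);
    const double tot = rsum(ii, w, 0, 0, win_h, win_w);
    const double tot2 = rsum(ii2, w, 0, 0, win_h, win_w);
    const double mu = tot / area;
    double var = tot2 / area - mu * mu;
    const double sd = var > 1e-12 ? std::sqrt(var) : 0.0;
    for (int f = 0; f < F; ++f) {
      if (sd == 0.0) { out(s, f) = 0.0; continue; }
      out(s, f) = feat_raw(ii, w, feats(f, 0), feats(f, 2), feats(f, 1),
                           feats(f, 3), feats(f, 4)) / sd;
    }
  }
  return out;
}

// Best decision stump under weighted 0-1 loss, exhaustive over features
// and thresholds. ord: 0-based sort orders per feature column of resp.
// labels in {-1, +1}. Prediction rule: +1 iff polarity*(value - thr) > 0.
// [[Rcpp::export]]
List cpp_best_stump(const NumericMatrix& resp,
                    const IntegerMatrix& ord,
                    const NumericVector& wts,
                    const IntegerVector& labels) {
  const int n = resp.nrow(), F = resp.ncol();
  double wpos = 0.0, wneg = 0.0;
  for (int i = 0; i < n; ++i) (labels[i] > 0 ? wpos : wneg) += wts[i];
  double best_err = 1e300, best_thr = 0.0;
  int best_f = -1, best_pol = 1;
  for (int f = 0; f < F; ++f) {
    double sp = 0.0, sn = 0.0;
    // threshold below the smallest value: all predicted right side
    {
      const double e_pos = wpos - sp + sn;     // polarity -1: +1 iff v < thr
      const double e_neg = sp + wneg - sn;     // polarity +1: +1 iff v > thr
      const double lo = resp(ord(0, f), f) - 1.0;
      if (e_neg < best_err) { best_err = e_neg; best_f = f; best_pol = 1; best_thr = lo; }
      if (e_pos < best_err) { best_err = e_pos; best_f = f; best_pol = -1; best_thr = lo; }
    }
    for (int i = 0; i < n; ++i) {
      const int idx = ord(i, f);
      (labels[idx] > 0 ? sp : sn) += wts[idx];
      const double v = resp(idx, f);
      const double vnext = (i == n - 1) ? v + 1.0 : resp(ord(i + 1, f), f);
      if (vnext == v) continue;
      const double thr = 0.5 * (v + vnext);
      // polarity +1: predict + for value > thr => errors: positives <= thr, negatives > thr
      const double e1 = sp + (wneg - sn);
      // polarity -1: predict + for value < thr
      const double e2 = (wpos - sp) + sn;
      if (e1 < best_err) { best_err = e1; best_f = f; best_pol = 1; best_thr = thr; }
      if (e2 < best_err) { best_err = e2; best_f = f; best_pol = -1; best_thr = thr; }
    }
  }
  return List::create(_["feature"] = best_f + 1, _["threshold"] = best_thr,
                      _["polarity"] = best_pol, _["error"] = best_err);
}

// Slide a fixed-size window over an image and evaluate the full cascade.
// Stumps are flattened: feats rows referenced 1-based by stump_feat.
// Returns integer matrix of accepted (x, y) window origins.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_cascade(const NumericMatrix& img,
                               int win_h, int win_w, int step,
                               const IntegerMatrix& feats,
                               const IntegerVector& stump_feat,
                               const NumericVector& stump_thr,
                               const IntegerVector& stump_pol,
                               const NumericVector& stump_left,
                               const NumericVector& stump_right,
                               const IntegerVector& stage_sizes,
                               const NumericVector& stage_thr) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> hx, hy;
  if (nr < win_h || nc < win_w)
    return IntegerMatrix(0, 2);
  std::vector<double> ii, ii2;
  integrals(img, ii, ii2, nr, nc);
  const int w = nc + 1;
  const double area = (double)win_h * win_w;
  const int nstage = stage_sizes.size();
  for (int y = 0; y + win_h <= nr; y += step) {
    for (int x = 0; x + win_w <= nc; x += step) {
      const double tot = rsum(ii, w, y, x, win_h, win_w);
      const double tot2 = rsum(ii2, w, y, x, win_h, win_w);
      const double mu = tot / area;
      double var = tot2 / area - mu * mu;
      const double sd = var > 1e-12 ? std::sqrt(var) : 0.0;
      if (sd == 0.0) continue;   // flat window: nothing to detect
      bool ok = true;
      int s0 = 0;
      for (int st = 0; st < nstage && ok; ++st) {
        double score = 0.0;
        for (int k = 0; k < stage_sizes[st]; ++k) {
          const int j = s0 + k;
          const int f = stump_feat[j] - 1;
          double v = 0.0;
          if (sd > 0.0)
            v = feat_raw(ii, w, feats(f, 0), y + feats(f, 2), x + feats(f, 1),
                         feats(f, 3), feats(f, 4)) / sd;
          score += (stump_pol[j] * (v - stump_thr[j]) > 0.0)
                     ? stump_right[j] : stump_left[j];
        }
        if (score < stage_thr[st]) ok = false;
        s0 += stage_sizes[st];
      }
      if (ok) { hx.push_back(x); hy.push_back(y); }
    }
  }
  IntegerMatrix out(hx.size(), 2);
  for (size_t i = 0; i < hx.size(); ++i) { out(i, 0) = hx[i]; out(i, 1) = hy[i]; }
  return out;
}

// Even-odd rasterization of a closed polygon onto a pixel grid: pixel
// (r, c) is set iff the count of polygon-edge crossings with x <= c on
// the scanline y = r is odd.
// [[Rcpp::export]]
LogicalMatrix cpp_rasterize_polygon(const NumericVector& px,
                                    const NumericVector& py,
                                    int nrow, int ncol) {
  LogicalMatrix out(nrow, ncol);
  const int n = px.size();
  if (n < 3) return out;
  std::vector<double> xs;
  for (int r = 0; r < nrow; ++r) {
    xs.clear();
    const double yr = (double)r;
    for (int i = 0; i < n; ++i) {
      const int j = (i + 1) % n;
      const double y1 = py[i], y2 = py[j];
      if ((y1 > yr) == (y2 > yr)) continue;
      xs.push_back(px[i] + (yr - y1) * (px[j] - px[i]) / (y2 - y1));
    }
    if (xs.empty()) continue;
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int c0 = (int)std::ceil(xs[k]);
      int c1 = (int)std::ceil(xs[k + 1]) - 1;
      if (c1 < 0 || c0 > ncol - 1) continue;  // span outside the grid
      c0 = clampi(c0, 0, ncol - 1);
      c1 = clampi(c1, 0, ncol - 1);
      for (int c = c0; c <= c1; ++c) out(r, c) = true;
    }
  }
  return out;
}

// Bilinear patch extraction around landmark centres, edge replication.
// Returns (ph*pw) x L matrix; within-patch layout column-major (rows fastest).
// [[Rcpp::export]]
NumericMatrix cpp_extract_patches(const NumericMatrix& img,
                                  const NumericVector& cx,
                                  const NumericVector& cy,
                                  int ph, int pw) {
  const int L = cx.size();
  const int hh = ph / 2, hw = pw / 2;
  NumericMatrix out(ph * pw, L);
  NumericVector xs(ph * pw), ys(ph * pw);
  for (int l = 0; l < L; ++l) {
    int k = 0;
    for (int dc = -hw; dc <= hw; ++dc)
      for (int dr = -hh; dr <= hh; ++dr) {
        xs[k] = cx[l] + dc;
        ys[k] = cy[l] + dr;
        ++k;
      }
    NumericVector v = cpp_interp_bilinear(img, xs, ys);
    for (int i = 0; i < ph * pw; ++i) out(i, l) = v[i];
  }
  return out;
}
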