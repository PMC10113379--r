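#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Window statistics for ZNCC. Returns false when the window has zero
// intensity variance (score undefined there).
static inline bool win_stats(const NumericMatrix &img, int cx, int cy, int r,
                             double &mean, double &norm) {
  double s = 0.0, s2 = 0.0;
  const int n = (2 * r + 1) * (2 * r + 1);
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      const double v = img(cy + dy, cx + dx);
      s += v;
      s2 += v * v;
    }
  mean = s / n;
  const double var = s2 - n * mean * mean;
  if (var <= 1e-12) return false;
  norm = std::sqrt(var);
  return true;
}

static inline double zncc_at(const NumericMatrix &a, int ax, int ay,
                             const NumericMatrix &b, int bx, int by, int r,
                             double amean, double anorm) {
  double bmean, bnorm;
  if (!win_stats(b, bx, by, r, bmean, bnorm)) return NA_REAL;
  double cross = 0.0;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      cross += (a(ay + dy, ax + dx) - amean) * (b(by + dy, bx + dx) - bmean);
  double s = cross / (anorm * bnorm);
  if (s > 1.0) s = 1.0;
  if (s < -1.0) s = -1.0;
  return s;
}

// ZNCC of two equally sized patches; NA when either has zero variance.
// [[Rcpp::export]]
double zncc_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() != b.nrow() || a.ncol() != b.ncol())
    stop("patches must have identical shapes");
  const int n = a.nrow() * a.ncol();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double va = 0, vb = 0, cr = 0;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    va += da * da; vb += db * db; cr += da * db;
  }
  if (va <= 1e-12 || vb <= 1e-12) return NA_REAL;
  double s = cr / std::sqrt(va * vb);
  if (s > 1.0) s = 1.0;
  if (s < -1.0) s = -1.0;
  return s;
}

// Dense integer-disparity block matching. left/right are intensity
// matrices (rows = y). A left pixel (x, y) is matched against right
// pixels (x - d, y) for d in [dmin, dmax]; ties broken toward the
// smallest disparity. Pixels with no admissible candidate, zero local
// variance, or best score below `thresh` are marked invalid.
// [[Rcpp::export]]
List disparity_map_cpp(NumericMatrix left, NumericMatrix right, int radius,
                       double thresh, int dmin, int dmax, bool lr_check) {
  const int h = left.nrow(), w = left.ncol();
  if (right.nrow() != h || right.ncol() != w)
    stop("left and right images must have the same size");
  if (radius < 1) stop("window radius must be >= 1");
  if (dmax < dmin) stop("search range is empty");
  IntegerMatrix disp(h, w);
  LogicalMatrix valid(h, w);
  NumericMatrix score(h, w);
  std::fill(disp.begin(), disp.end(), 0);
  std::fill(score.begin(), score.end(), NA_REAL);

  // restrict to the overlap region: columns where the whole search range is
  // admissible (a truncated range cannot contain the true disparity and
  // would only produce structurally unreliable matches)
  for (int y = radius; y < h - radius; ++y) {
    for (int x = radius + dmax; x < w - radius; ++x) {
      double lmean, lnorm;
      if (!win_stats(left, x, y, radius, lmean, lnorm)) continue;
      double best = -2.0;
      int bestd = -1;
      for (int d = dmin; d <= dmax; ++d) {
        const double s =
            zncc_at(left, x, y, right, x - d, y, radius, lmean, lnorm);
        if (NumericMatrix::is_na(s)) continue;
        if (s > best) { best = s; bestd = d; }
      }
      if (bestd >= 0 && best >= thresh) {
        disp(y, x) = bestd;
        valid(y, x) = true;
        score(y, x) = best;
      }
    }
  }
  if (lr_check) {
    // right-to-left pass: occluded or ambiguous pixels match inconsistently
    // and are invalidated (they show up black in the exported map)
    IntegerMatrix rdisp(h, w);
    LogicalMatrix rvalid(h, w);
    for (int y = radius; y < h - radius; ++y) {
      for (int x = radius; x < w - radius - dmax; ++x) {
        double rmean, rnorm;
        if (!win_stats(right, x, y, radius, rmean, rnorm)) continue;
        double best = -2.0;
        int bestd = -1;
        for (int d = dmin; d <= dmax; ++d) {
          const double s =
              zncc_at(right, x, y, left, x + d, y, radius, rmean, rnorm);
          if (NumericMatrix::is_na(s)) continue;
          if (s > best) { best = s; bestd = d; }
        }
        if (bestd >= 0 && best >= thresh) {
          rdisp(y, x) = bestd;
          rvalid(y, x) = true;
        }
      }
    }
    for (int y = 0; y < h; ++y)
      for (int x = 0; x < w; ++x) {
        if (!valid(y, x)) continue;
        const int xr = x - disp(y, x);
        if (xr < 0 || !rvalid(y, xr) ||
            std::abs(rdisp(y, xr) - disp(y, x)) > 1) {
          valid(y, x) = false;
          disp(y, x) = 0;
          score(y, x) = NA_REAL;
        }
      }
  }
  return List::create(_["disparity"] = disp, _["valid"] = valid,
                      _["score"] = score);
}

// Parabolic sub-pixel refinement of a score peak sampled at spacing h.
static inline double parabolic_offset(double sm, double s0, double sp,
                                      double h) {
  const double den = sm - 2.0 * s0 + sp;
  if (!(den < -1e-12)) return 0.0;  // not a proper maximum
  double off = h * 0.5 * (sm - sp) / den;
  if (off > h) off = h;
  if (off < -h) off = -h;
  return off;
}

// ZNCC of the left window at (ax, ay) against a bilinearly interpolated
// right window centred at fractional (bx, by).
static double zncc_at_frac(const NumericMatrix &a, int ax, int ay,
                           const NumericMatrix &b, double bx, double by,
                           int r, double amean, double anorm) {
  const int x0 = (int)std::floor(bx), y0 = (int)std::floor(by);
  const double fx = bx - x0, fy = by - y0;
  if (x0 - r < 0 || y0 - r < 0 || x0 + r + 1 >= b.ncol() ||
      y0 + r + 1 >= b.nrow())
    return NA_REAL;
  const int n = (2 * r + 1) * (2 * r + 1);
  double s = 0, s2 = 0, cr = 0;
  // first pass: interpolated window statistics
  double vals[1024];
  int idx = 0;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      const int yy = y0 + dy, xx = x0 + dx;
      const double v =
          (1 - fy) * ((1 - fx) * b(yy, xx) + fx * b(yy, xx + 1)) +
          fy * ((1 - fx) * b(yy + 1, xx) + fx * b(yy + 1, xx + 1));
      vals[idx++] = v;
      s += v;
      s2 += v * v;
    }
  const double bmean = s / n;
  const double bvar = s2 - n * bmean * bmean;
  if (bvar <= 1e-12 || std::isnan(bvar)) return NA_REAL;
  idx = 0;
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx)
      cr += (a(ay + dy, ax + dx) - amean) * (vals[idx++] - bmean);
  double sc = cr / (anorm * std::sqrt(bvar));
  if (sc > 1.0) sc = 1.0;
  if (sc < -1.0) sc = -1.0;
  return sc;
}

// 2-D ZNCC search used by calibration: for each left point (xs, ys)
// (0-based), search right in x offsets [dxmin, dxmax] and y offsets
// [dymin, dymax]; ties broken toward the smallest (dy, dx). The integer
// peak is refined to sub-pixel precision by parabolic interpolation of
// the score along each axis. Returns an n x 4 matrix
// (x_right, y_right, score, ok).
// [[Rcpp::export]]
NumericMatrix match_points2d_cpp(NumericMatrix left, NumericMatrix right,
                                 IntegerVector xs, IntegerVector ys,
                                 int radius, int dxmin, int dxmax, int dymin,
                                 int dymax, double thresh) {
  const int h = left.nrow(), w = left.ncol();
  const int hr = right.nrow(), wr = right.ncol();
  const int n = xs.size();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    const int x = xs[i], y = ys[i];
    out(i, 3) = 0.0;
    if (x < radius || x >= w - radius || y < radius || y >= h - radius)
      continue;
    double lmean, lnorm;
    if (!win_stats(left, x, y, radius, lmean, lnorm)) continue;
    double best = -2.0;
    int bx = -1, by = -1;
    for (int dy = dymin; dy <= dymax; ++dy) {
      const int yy = y + dy;
      if (yy < radius || yy >= hr - radius) continue;
      for (int dx = dxmin; dx <= dxmax; ++dx) {
        const int xx = x + dx;
        if (xx < radius || xx >= wr - radius) continue;
        const double s = zncc_at(left, x, y, right, xx, yy, radius, lmean, lnorm);
        if (NumericMatrix::is_na(s)) continue;
        if (s > best) { best = s; bx = xx; by = yy; }
      }
    }
    if (bx >= 0 && best >= thresh) {
      // two-stage sub-pixel refinement on interpolated windows: parabola on
      // a half-pixel grid, then a quarter-pixel parabola centred on the
      // first estimate. Coarser (whole-pixel) refinement leaves a
      // pixel-locking bias that is constant along a scanline and would
      // alias into the rotation estimates.
      double sx = 0.0, sy = 0.0;
      if ((2 * radius + 1) * (2 * radius + 1) <= 1024) {
        for (int stage = 0; stage < 2; ++stage) {
          const double hh = stage == 0 ? 0.5 : 0.25;
          const double s0 =
              stage == 0 ? best
                         : zncc_at_frac(left, x, y, right, bx + sx, by + sy,
                                        radius, lmean, lnorm);
          if (NumericMatrix::is_na(s0)) break;
          const double smx = zncc_at_frac(left, x, y, right, bx + sx - hh,
                                          by + sy, radius, lmean, lnorm);
          const double spx = zncc_at_frac(left, x, y, right, bx + sx + hh,
                                          by + sy, radius, lmean, lnorm);
          if (!NumericMatrix::is_na(smx) && !NumericMatrix::is_na(spx))
            sx += parabolic_offset(smx, s0, spx, hh);
          const double smy = zncc_at_frac(left, x, y, right, bx + sx,
                                          by + sy - hh, radius, lmean, lnorm);
          const double spy = zncc_at_frac(left, x, y, right, bx + sx,
                                          by + sy + hh, radius, lmean, lnorm);
          if (!NumericMatrix::is_na(smy) && !NumericMatrix::is_na(spy))
            sy += parabolic_offset(smy, s0, spy, hh);
        }
      }
      out(i, 0) = bx + sx;
      out(i, 1) = by + sy;
      out(i, 2) = best;
      out(i, 3) = 1.0;
    }
  }
  return out;
}

// Catmull-Rom weights for fractional offset t.
static inline void catmull_w(double t, double w[4]) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] = 1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] = 0.5 * t3 - 0.5 * t2;
}

// Inverse-map warp. H (3x3) maps OUTPUT homogeneous centred pixel
// coordinates to INPUT centred coordinates; cx, cy is the centre (0-based
// pixels). Samples outside the input are NA. Interpolation is Catmull-Rom
// bicubic (falling back to bilinear within one pixel of the border):
// bilinear resampling blurs the texture anisotropically and imprints a
// position-dependent matching bias on anything estimated from the warped
// image.
// [[Rcpp::export]]
NumericMatrix warp_bilinear_cpp(NumericMatrix img, NumericMatrix H, double cx,
                                double cy) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);
  std::fill(out.begin(), out.end(), NA_REAL);
  const double h00 = H(0, 0), h01 = H(0, 1), h02 = H(0, 2);
  const double h10 = H(1, 0), h11 = H(1, 1), h12 = H(1, 2);
  const double h20 = H(2, 0), h21 = H(2, 1), h22 = H(2, 2);
  for (int y = 0; y < h; ++y) {
    const double v = y - cy;
    for (int x = 0; x < w; ++x) {
      const double u = x - cx;
      const double zw = h20 * u + h21 * v + h22;
      if (std::fabs(zw) < 1e-12) continue;
      const double xs = (h00 * u + h01 * v + h02) / zw + cx;
      const double ys = (h10 * u + h11 * v + h12) / zw + cy;
      const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      if (x0 < 0 || y0 < 0 || x0 >= w - 1 || y0 >= h - 1) continue;
      const double fx = xs - x0, fy = ys - y0;
      if (x0 >= 1 && y0 >= 1 && x0 < w - 2 && y0 < h - 2) {
        double wx[4], wy[4];
        catmull_w(fx, wx);
        catmull_w(fy, wy);
        double acc = 0.0;
        for (int j = 0; j < 4; ++j) {
          double row = 0.0;
          for (int i = 0; i < 4; ++i)
            row += wx[i] * img(y0 - 1 + j, x0 - 1 + i);
          acc += wy[j] * row;
        }
        out(y, x) = acc;
      } else {
        out(y, x) =
            (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x0 + 1)) +
            fy * ((1 - fx) * img(y0 + 1, x0) + fx * img(y0 + 1, x0 + 1));
      }
    }
  }
  return out;
}
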