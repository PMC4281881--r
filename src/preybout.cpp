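#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// bilinear sample of img (H x W, row = y, col = x) at 0-based pixel coords;
// outside the image returns `fill`
static inline double bilinear(const NumericMatrix& img, double x, double y,
                              double fill) {
  const int H = img.nrow(), W = img.ncol();
  if (x < 0 || y < 0 || x > W - 1 || y > H - 1) return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, W - 1), y1 = std::min(y0 + 1, H - 1);
  double fx = x - x0, fy = y - y0;
  double v00 = img(y0, x0), v01 = img(y0, x1);
  double v10 = img(y1, x0), v11 = img(y1, x1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy * ((1 - fx) * v10 + fx * v11);
}

// zero-padded 'same' convolution of v with a symmetric odd-length kernel
static std::vector<double> conv_same(const std::vector<double>& v,
                                     const NumericVector& k) {
  const int n = (int)v.size(), m = k.size(), h = m / 2;
  std::vector<double> out(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) {
      int idx = i + j - h;
      if (idx >= 0 && idx < n) s += v[idx] * k[j];
    }
    out[i] = s;
  }
  return out;
}

// Stamp the tail midline onto each frame as a bright stroke with a Gaussian
// cross-section (max-combined so overlapping stamps do not sum).
// dense_pts: list of (n_i x 2) matrices of 0-based (x, y) midline samples
// at ~1 px arc spacing. Returns an H x W x T array (background 0).
// [[Rcpp::export]]
NumericVector cpp_render_frames(List dense_pts, int H, int W, double sigma,
                                double contrast, double background,
                                double noise_sd) {
  const int T = dense_pts.size();
  NumericVector out(Dimension(H, W, T));
  const int rad = (int)std::ceil(3.0 * sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int t = 0; t < T; ++t) {
    NumericMatrix pts = dense_pts[t];
    double* frame = &out[(R_xlen_t)t * H * W];
    for (int i = 0; i < pts.nrow(); ++i) {
      const double px = pts(i, 0), py = pts(i, 1);
      const int c0 = std::max(0, (int)std::floor(px) - rad);
      const int c1 = std::min(W - 1, (int)std::ceil(px) + rad);
      const int r0 = std::max(0, (int)std::floor(py) - rad);
      const int r1 = std::min(H - 1, (int)std::ceil(py) + rad);
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          const double dx = c - px, dy = r - py;
          const double v = contrast * std::exp(-(dx * dx + dy * dy) * inv2s2);
          double& cell = frame[(R_xlen_t)c * H + r];
          if (v > cell) cell = v;
        }
      }
    }
  }
  // dark noisy background under the stroke, clamped to 8-bit range
  RNGScope rng;
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = out[i] + background;
    if (noise_sd > 0) v += noise_sd * R::norm_rand();
    out[i] = std::min(255.0, std::max(0.0, v));
  }
  return out;
}

// Ridge-following tail tracker for one frame.
// From the base point, iteratively: extrapolate the next midpoint, sample an
// intensity slice perpendicular to the current direction (1 px spacing,
// bilinear), smooth it, convolve with the matched tail-profile kernel, and
// take the (parabolically refined) maximum as the midpoint. Stops when the
// luminance change across the smoothed slice (peak minus slice median) drops
// below stop_level, or the slice centre leaves the image.
// Returns an n x 2 matrix of 0-based (x, y) points starting at the base.
// [[Rcpp::export]]
NumericMatrix cpp_track_frame(NumericMatrix img, double bx, double by,
                              double hx, double hy, double step,
                              NumericVector smooth_kernel,
                              NumericVector match_kernel, int half_slice,
                              double stop_level, int max_pts, double fill,
                              double trim_level) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<double> xs, ys;
  xs.push_back(bx);
  ys.push_back(by);
  double dn = std::sqrt(hx * hx + hy * hy);
  double dx = hx / dn, dy = hy / dn;
  double px = bx, py = by;
  const int ns = 2 * half_slice + 1;
  std::vector<double> slice(ns);
  while ((int)xs.size() < max_pts) {
    const double cx = px + step * dx, cy = py + step * dy;
    if (cx < 1 || cy < 1 || cx > W - 2 || cy > H - 2) break;
    const double ux = -dy, uy = dx;  // perpendicular unit vector
    for (int j = 0; j < ns; ++j) {
      const double o = (double)(j - half_slice);
      slice[j] = bilinear(img, cx + o * ux, cy + o * uy, fill);
    }
    std::vector<double> sm = conv_same(slice, smooth_kernel);
    // end-of-tail test: luminance change across the slice
    std::vector<double> sorted(slice);
    std::nth_element(sorted.begin(), sorted.begin() + ns / 2, sorted.end());
    const double med = sorted[ns / 2];
    const double peak = *std::max_element(sm.begin(), sm.end());
    if (peak - med < stop_level) break;
    std::vector<double> resp = conv_same(sm, match_kernel);
    // argmax; ties broken toward the predicted midpoint (slice centre)
    int best = 0;
    for (int j = 1; j < ns; ++j) {
      if (resp[j] > resp[best] ||
          (resp[j] == resp[best] &&
           std::abs(j - half_slice) < std::abs(best - half_slice)))
        best = j;
    }
    double off = (double)(best - half_slice);
    if (best > 0 && best < ns - 1) {  // sub-pixel parabolic refinement
      const double denom = resp[best - 1] - 2.0 * resp[best] + resp[best + 1];
      if (denom < 0)
        off += 0.5 * (resp[best - 1] - resp[best + 1]) / denom;
    }
    const double nx = cx + off * ux, ny = cy + off * uy;
    const double sx = nx - px, sy = ny - py;
    const double sl = std::sqrt(sx * sx + sy * sy);
    if (sl < 1e-9) break;
    dx = sx / sl;
    dy = sy / sl;
    px = nx;
    py = ny;
    xs.push_back(px);
    ys.push_back(py);
  }
  // trim trailing points that walked past the tail tip (image intensity
  // below trim_level, typically background + half the calibrated contrast)
  while (xs.size() > 1 &&
         bilinear(img, xs.back(), ys.back(), fill) < trim_level) {
    xs.pop_back();
    ys.pop_back();
  }
  NumericMatrix out((int)xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}

// Sliding-window percentile per column of a T x n matrix (centered window,
// truncated at the edges). The percentile uses linear interpolation between
// order statistics: h = (m - 1) * p + 1 on the sorted window of length m
// (the convention of stats::quantile type 7).
// [[Rcpp::export]]
NumericMatrix cpp_sliding_percentile(NumericMatrix x, int window,
                                     double prob) {
  const int T = x.nrow(), n = x.ncol();
  const int half = window / 2;
  NumericMatrix out(T, n);
  std::vector<double> buf;
  buf.reserve(window);
  for (int j = 0; j < n; ++j) {
    for (int t = 0; t < T; ++t) {
      const int lo = std::max(0, t - half);
      const int hi = std::min(T - 1, t + half);
      const int m = hi - lo + 1;
      buf.assign(&x(lo, j), &x(lo, j) + m);
      std::sort(buf.begin(), buf.end());
      const double h = (m - 1) * prob;
      const int fl = (int)std::floor(h);
      const double frac = h - fl;
      double v = buf[fl];
      if (frac > 0 && fl + 1 < m) v += frac * (buf[fl + 1] - buf[fl]);
      out(t, j) = v;
    }
  }
  return out;
}
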