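#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

#define MAX_WIN 121  // windows up to 11 x 11

// median of the first n entries of a small scratch buffer (reorders it)
static double med_of(double *v, int n) {
  if (n == 0) return NA_REAL;
  std::nth_element(v, v + n / 2, v + n);
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v, v + n / 2 - 1, v + n / 2);
  return 0.5 * (hi + v[n / 2 - 1]);
}

static inline void sorted_insert(double *buf, int &n, double v) {
  double *pos = std::lower_bound(buf, buf + n, v);
  std::memmove(pos + 1, pos, (buf + n - pos) * sizeof(double));
  *pos = v;
  ++n;
}

static inline void sorted_remove(double *buf, int &n, double v) {
  double *pos = std::lower_bound(buf, buf + n, v);
  std::memmove(pos, pos + 1, (buf + n - pos - 1) * sizeof(double));
  --n;
}

// median absolute deviation about m of a sorted buffer, by outward
// two-pointer merge of the left (decreasing) and right (increasing)
// deviation sequences
static double mad_sorted(const double *buf, int n, double m) {
  int split = (int)(std::lower_bound(buf, buf + n, m) - buf);
  int lo = split - 1, hi = split;
  int k1 = (n - 1) / 2, k2 = n / 2;   // 0-indexed order stats to average
  double d1 = 0, d2 = 0;
  for (int t = 0; t <= k2; ++t) {
    double dl = lo >= 0 ? m - buf[lo] : R_PosInf;
    double dr = hi < n ? buf[hi] - m : R_PosInf;
    double d;
    if (dl <= dr) { d = dl; --lo; } else { d = dr; ++hi; }
    if (t == k1) d1 = d;
    if (t == k2) d2 = d;
  }
  return 0.5 * (d1 + d2);
}

//' @name cpp_filters
//' @title Local median and MAD (sliding window)
//' @description For each pixel, the median and the median absolute deviation
//'   of the w x w neighborhood including the center pixel; windows are
//'   clamped at the image border. A sorted sliding window is maintained down
//'   each column band, so the cost per pixel is O(w). Used by the spike/dip
//'   detector; not exported to users.
//' @keywords internal
// [[Rcpp::export(name = ".localMedianMad")]]
List localMedianMad(NumericMatrix img, int w) {
  const int H = img.nrow(), W = img.ncol(), h = (w - 1) / 2;
  if (w * w > MAX_WIN) stop("window too large");
  if (w % 2 == 0 || w < 3) stop("window must be odd and >= 3");
  NumericMatrix med(H, W), mad(H, W);
  const double *px = &img(0, 0);
  double buf[MAX_WIN];
  for (int j = 0; j < W; ++j) {
    const int c0 = std::max(0, j - h), c1 = std::min(W - 1, j + h);
    int n = 0;
    for (int r = 0; r <= std::min(h, H - 1); ++r)
      for (int c = c0; c <= c1; ++c)
        sorted_insert(buf, n, px[(R_xlen_t)c * H + r]);
    for (int i = 0; i < H; ++i) {
      if (i > 0) {
        const int rOut = i - 1 - h, rIn = i + h;
        if (rOut >= 0)
          for (int c = c0; c <= c1; ++c)
            sorted_remove(buf, n, px[(R_xlen_t)c * H + rOut]);
        if (rIn <= H - 1)
          for (int c = c0; c <= c1; ++c)
            sorted_insert(buf, n, px[(R_xlen_t)c * H + rIn]);
      }
      const double m = (n % 2) ? buf[n / 2] : 0.5 * (buf[n / 2 - 1] + buf[n / 2]);
      med(i, j) = m;
      mad(i, j) = mad_sorted(buf, n, m);
    }
  }
  return List::create(_["median"] = med, _["mad"] = mad);
}

//' @name cpp_repair
//' @title Replace flagged pixels by the neighborhood median of clean pixels
//' @description Each flagged pixel is replaced by the median of the
//'   non-flagged pixels in its w x w window (center excluded); if the window
//'   holds no clean pixel the supplied fallback value is used. Non-flagged
//'   pixels pass through unchanged; replacements all read from the original
//'   image so the result does not depend on pixel visiting order.
//' @keywords internal
// [[Rcpp::export(name = ".medianRepair")]]
NumericMatrix medianRepair(NumericMatrix img, LogicalMatrix flag, int w,
                           double fallback) {
  const int H = img.nrow(), W = img.ncol(), h = (w - 1) / 2;
  if (w * w > MAX_WIN) stop("window too large");
  NumericMatrix out(clone(img));
  double buf[MAX_WIN];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!flag(i, j)) continue;
      int n = 0;
      const int r0 = std::max(0, i - h), r1 = std::min(H - 1, i + h);
      const int c0 = std::max(0, j - h), c1 = std::min(W - 1, j + h);
      for (int c = c0; c <= c1; ++c)
        for (int r = r0; r <= r1; ++r)
          if (!(r == i && c == j) && !flag(r, c)) buf[n++] = img(r, c);
      out(i, j) = n == 0 ? fallback : med_of(buf, n);
    }
  }
  return out;
}
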