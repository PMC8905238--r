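// Low-level raster operations used by the segmentation and preprocessing
// stages: 8-connected component labeling, marker-controlled flooding on an
// altitude surface, and bilinear resampling (resize / center rotation).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// 8-connected component labeling of a logical matrix. Components are numbered
// 1..K in raster-scan order (column-major, as R stores matrices) of their
// first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

namespace {
struct QEntry {
  double alt;     // altitude (lower floods first)
  long   seq;     // FIFO tie-break: equal-altitude fronts advance uniformly
  int    idx;     // linear pixel index
  int    lab;     // candidate basin label
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.alt != b.alt) return a.alt > b.alt;
    return a.seq > b.seq;
  }
};
} // namespace

// Marker-controlled flooding (Meyer's algorithm) over `altitude`, restricted
// to `region`. Every region pixel ends up assigned to one marker basin;
// ridge/tie pixels go to whichever equal-altitude front arrives first, which
// with the FIFO tie-break is the nearer marker. 8-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_flood(const NumericMatrix& altitude,
                               const IntegerMatrix& markers,
                               const LogicalMatrix& region) {
  const int H = altitude.nrow(), W = altitude.ncol();
  if (markers.nrow() != H || markers.ncol() != W ||
      region.nrow() != H || region.ncol() != W)
    stop("altitude, markers and region must have identical dimensions");
  IntegerMatrix lab(H, W);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  long seq = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (markers(r, c) > 0 && region(r, c)) {
        lab(r, c) = markers(r, c);
      }
  // seed the queue with unlabeled region neighbors of marker pixels
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) == 0) continue;
      for (int dc = -1; dc <= 1; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          int nr = r + dr, nc = c + dc;
          if ((dr == 0 && dc == 0) || nr < 0 || nr >= H || nc < 0 || nc >= W)
            continue;
          if (region(nr, nc) && lab(nr, nc) == 0)
            pq.push({altitude(nr, nc), seq++, nr + nc * H, lab(r, c)});
        }
    }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    int r = e.idx % H, c = e.idx / H;
    if (lab(r, c) != 0) continue;
    lab(r, c) = e.lab;
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        int nr = r + dr, nc = c + dc;
        if ((dr == 0 && dc == 0) || nr < 0 || nr >= H || nc < 0 || nc >= W)
          continue;
        if (region(nr, nc) && lab(nr, nc) == 0)
          pq.push({altitude(nr, nc), seq++, nr + nc * H, e.lab});
      }
  }
  return lab;
}

static inline double bilinear_at(const double* plane, int H, int W,
                                 double sr, double sc) {
  // clamp-to-edge sampling at fractional (row, col)
  if (sr < 0) sr = 0; if (sr > H - 1) sr = H - 1;
  if (sc < 0) sc = 0; if (sc > W - 1) sc = W - 1;
  int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
  int r1 = std::min(r0 + 1, H - 1), c1 = std::min(c0 + 1, W - 1);
  double fr = sr - r0, fc = sc - c0;
  double v00 = plane[r0 + c0 * H], v10 = plane[r1 + c0 * H];
  double v01 = plane[r0 + c1 * H], v11 = plane[r1 + c1 * H];
  return (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
         (1 - fr) * fc * v01 + fr * fc * v11;
}

// Round and clip to the 8-bit range in one pass (hot path of the scene
// generator).
// [[Rcpp::export]]
IntegerVector cpp_clip_round_u8(const NumericVector& x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = std::nearbyint(x[i]);
    out[i] = v < 0 ? 0 : (v > 255 ? 255 : (int)v);
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Bilinear resize of an H x W x C array to out_h x out_w x C. Pixel centers
// align: source coord = (i + 0.5) * scale - 0.5 (identity when sizes match).
// Set `nearest` for nearest-neighbor resampling instead.
// [[Rcpp::export]]
NumericVector cpp_resize(const NumericVector& img, int out_h, int out_w,
                         bool nearest = false) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("img must be an H x W x C array");
  const int H = d[0], W = d[1], C = d[2];
  if (out_h < 1 || out_w < 1) stop("output size must be positive");
  NumericVector out(out_h * (R_xlen_t)out_w * C);
  out.attr("dim") = IntegerVector::create(out_h, out_w, C);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int ch = 0; ch < C; ++ch) {
    const double* plane = &img[(R_xlen_t)ch * H * W];
    double* oplane = &out[(R_xlen_t)ch * out_h * out_w];
    for (int c = 0; c < out_w; ++c) {
      double sc = (c + 0.5) * sx - 0.5;
      for (int r = 0; r < out_h; ++r) {
        double sr = (r + 0.5) * sy - 0.5;
        if (nearest) {
          int nr = std::min(H - 1, std::max(0, (int)std::lround(sr)));
          int nc = std::min(W - 1, std::max(0, (int)std::lround(sc)));
          oplane[r + c * out_h] = plane[nr + nc * H];
        } else {
          oplane[r + c * out_h] = bilinear_at(plane, H, W, sr, sc);
        }
      }
    }
  }
  return out;
}

// Same-size rotation about the image center by `angle` radians
// (counter-clockwise in standard row/col image coordinates), bilinear
// sampling, out-of-frame pixels set to `fill`.
// [[Rcpp::export]]
NumericVector cpp_rotate(const NumericVector& img, double angle, double fill) {
  IntegerVector d = img.attr("dim");
  if (d.size() != 3) stop("img must be an H x W x C array");
  const int H = d[0], W = d[1], C = d[2];
  NumericVector out(img.size());
  out.attr("dim") = d;
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  for (int ch = 0; ch < C; ++ch) {
    const double* plane = &img[(R_xlen_t)ch * H * W];
    double* oplane = &out[(R_xlen_t)ch * H * W];
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        // inverse mapping: rotate destination offset back into source
        double dy = r - cy, dx = c - cx;
        double sr = cy + ca * dy + sa * dx;
        double sc = cx - sa * dy + ca * dx;
        if (sr < -0.5 || sr > H - 0.5 || sc < -0.5 || sc > W - 0.5)
          oplane[r + c * H] = fill;
        else
          oplane[r + c * H] = bilinear_at(plane, H, W, sr, sc);
      }
    }
  }
  return out;
}
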