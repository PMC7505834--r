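#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared pixel-level kernels. Images are R matrices indexed [row, col] =
// [y, x]; all neighborhood code uses replicate padding at the borders.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Offsets of the circular disc dx^2 + dy^2 <= r^2 (inclusive).
static void disc_offsets(int radius, std::vector<int>& dy, std::vector<int>& dx) {
  const int r2 = radius * radius;
  for (int j = -radius; j <= radius; ++j)
    for (int i = -radius; i <= radius; ++i)
      if (i * i + j * j <= r2) { dy.push_back(i); dx.push_back(j); }
}

// Smallest t in [0,255] maximizing Otsu between-class variance for the
// partition {<= t} vs {> t}.  Degenerate (single occupied bin) histograms
// return that bin's value.
static int otsu_from_hist(const std::vector<long>& h) {
  long total = 0; double sum = 0.0;
  int lo = -1, hi = -1;
  for (int i = 0; i < 256; ++i) {
    total += h[i];
    sum += (double)i * h[i];
    if (h[i] > 0) { if (lo < 0) lo = i; hi = i; }
  }
  if (total == 0) return 0;
  if (lo == hi) return lo;
  double best = -1.0; int best_t = lo;
  long w0 = 0; double sum0 = 0.0;
  for (int t = lo; t < hi; ++t) {
    w0 += h[t]; sum0 += (double)t * h[t];
    long w1 = total - w0;
    if (w0 == 0 || w1 == 0) continue;
    double mu0 = sum0 / w0, mu1 = (sum - sum0) / w1;
    double bc = (double)w0 * (double)w1 * (mu0 - mu1) * (mu0 - mu1);
    if (bc > best + 1e-9) { best = bc; best_t = t; }
  }
  return best_t;
}

// Column-sliding neighbourhood scan.  For every pixel the 256-bin
// histogram and first two moments of the disc neighbourhood are maintained
// incrementally while moving down a column: only the 2*(2r+1) cells
// entering/leaving the disc change.  Two border modes: replicate (index
// clamping; clamped add/remove commute with the update) and clip (cells
// outside the image are excluded and the neighbourhood count varies).
template <typename PerPixel>
static void local_scan(const IntegerMatrix& img, int radius, bool clip,
                       PerPixel f) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> hmax(2 * radius + 1);   // disc half-height per dx offset
  for (int dx = -radius; dx <= radius; ++dx)
    hmax[dx + radius] = (int)std::floor(std::sqrt((double)radius * radius - (double)dx * dx));
  std::vector<long> h(256);
  for (int c = 0; c < nc; ++c) {
    std::fill(h.begin(), h.end(), 0L);
    double s = 0.0, s2 = 0.0;
    long nn = 0;
    for (int dx = -radius; dx <= radius; ++dx) {
      if (clip && (c + dx < 0 || c + dx >= nc)) continue;
      int cc = clampi(c + dx, 0, nc - 1);
      for (int dy = -hmax[dx + radius]; dy <= hmax[dx + radius]; ++dy) {
        if (clip && (dy < 0 || dy >= nr)) continue;
        int v = img(clampi(dy, 0, nr - 1), cc);
        ++h[v]; s += v; s2 += (double)v * v; ++nn;
      }
    }
    f(0, c, h, s, s2, nn);
    for (int r = 1; r < nr; ++r) {
      for (int dx = -radius; dx <= radius; ++dx) {
        if (clip && (c + dx < 0 || c + dx >= nc)) continue;
        int cc = clampi(c + dx, 0, nc - 1);
        int hm = hmax[dx + radius];
        if (!clip || r - 1 - hm >= 0) {
          int vOut = img(clampi(r - 1 - hm, 0, nr - 1), cc);
          --h[vOut]; s -= vOut; s2 -= (double)vOut * vOut;
          if (clip) --nn;
        }
        if (!clip || r + hm < nr) {
          int vIn = img(clampi(r + hm, 0, nr - 1), cc);
          ++h[vIn]; s += vIn; s2 += (double)vIn * vIn;
          if (clip) ++nn;
        }
      }
      f(r, c, h, s, s2, nn);
    }
  }
}

// [[Rcpp::export]]
List cpp_local_fields(IntegerMatrix img, int radius, bool clip) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix mean_(nr, nc), sd_(nr, nc), med_(nr, nc), n_(nr, nc);
  IntegerMatrix min_(nr, nc), max_(nr, nc);
  local_scan(img, radius, clip,
    [&](int r, int c, const std::vector<long>& h, double s, double s2, long nn) {
      n_(r, c) = (double)nn;
      double mu = s / nn;
      double var = s2 / nn - mu * mu;
      mean_(r, c) = mu;
      sd_(r, c) = var > 0 ? std::sqrt(var) : 0.0;
      int mn = 0; while (mn < 255 && h[mn] == 0) ++mn;
      int mx = 255; while (mx > 0 && h[mx] == 0) --mx;
      min_(r, c) = mn;
      max_(r, c) = mx;
      const long half = (nn + 1) / 2;  // lower median rank
      long cum = 0; int m = 0;
      for (int v = 0; v < 256; ++v) { cum += h[v]; if (cum >= half) { m = v; break; } }
      med_(r, c) = m;
    });
  return List::create(_["mean"] = mean_, _["sd"] = sd_, _["min"] = min_,
                      _["max"] = max_, _["median"] = med_,
                      _["n"] = n_);
}

// [[Rcpp::export]]
IntegerMatrix cpp_local_otsu(IntegerMatrix img, int radius, bool clip) {
  IntegerMatrix t_(img.nrow(), img.ncol());
  local_scan(img, radius, clip,
    [&](int r, int c, const std::vector<long>& h, double, double, long) {
      t_(r, c) = otsu_from_hist(h);
    });
  return t_;
}

// 8- or 4-connected component labelling (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int>> nbr;
  nbr.push_back(std::make_pair(-1, 0)); nbr.push_back(std::make_pair(1, 0));
  nbr.push_back(std::make_pair(0, -1)); nbr.push_back(std::make_pair(0, 1));
  if (connectivity == 8) {
    nbr.push_back(std::make_pair(-1, -1)); nbr.push_back(std::make_pair(-1, 1));
    nbr.push_back(std::make_pair(1, -1)); nbr.push_back(std::make_pair(1, 1));
  }
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back(); stack.pop_back();
        for (size_t k = 0; k < nbr.size(); ++k) {
          int rr = p.first + nbr[k].first, cc = p.second + nbr[k].second;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

static inline double sample_bilinear(const NumericMatrix& img, double y, double x) {
  const int nr = img.nrow(), nc = img.ncol();
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  double fy = y - y0, fx = x - x0;
  int y0c = clampi(y0, 0, nr - 1), y1c = clampi(y0 + 1, 0, nr - 1);
  int x0c = clampi(x0, 0, nc - 1), x1c = clampi(x0 + 1, 0, nc - 1);
  return (1 - fy) * ((1 - fx) * img(y0c, x0c) + fx * img(y0c, x1c)) +
         fy * ((1 - fx) * img(y1c, x0c) + fx * img(y1c, x1c));
}

// Rigid resampling: output(p) = input(R^{-1}(p - centre - t) + centre),
// i.e. the returned image is the input rotated by theta (about the image
// centre) then translated by (dx, dy) pixels; bilinear interpolation with
// replicate padding.  dx moves content rightwards (+x = columns), dy
// downwards (+y = rows).
// [[Rcpp::export]]
NumericMatrix cpp_warp_rigid(NumericMatrix img, double dx, double dy, double theta_deg) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (nr - 1) / 2.0, cx = (nc - 1) / 2.0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double py = r - cy - dy, px = c - cx - dx;
      double sy = -st * px + ct * py + cy;
      double sx = ct * px + st * py + cx;
      out(r, c) = sample_bilinear(img, sy, sx);
    }
  }
  return out;
}

// Deformation by a per-pixel displacement field: out(y,x) = in(y + dyf, x + dxf).
// [[Rcpp::export]]
NumericMatrix cpp_warp_field(NumericMatrix img, NumericMatrix dyf, NumericMatrix dxf) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = sample_bilinear(img, r + dyf(r, c), c + dxf(r, c));
  return out;
}

// Zhang-Suen binary thinning to a 1-px skeleton; iterates the two
// sub-passes until no pixel changes.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> a(nr * nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      a[r + nr * c] = mask(r, c) ? 1 : 0;
  std::vector<int> kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!a[r + nr * c]) continue;
          // neighbours P2..P9 clockwise from north, 0 outside the image
          int p[8];
          int rm = r - 1, rp = r + 1, cm = c - 1, cp = c + 1;
          p[0] = (rm >= 0) ? a[rm + nr * c] : 0;                    // N
          p[1] = (rm >= 0 && cp < nc) ? a[rm + nr * cp] : 0;        // NE
          p[2] = (cp < nc) ? a[r + nr * cp] : 0;                    // E
          p[3] = (rp < nr && cp < nc) ? a[rp + nr * cp] : 0;        // SE
          p[4] = (rp < nr) ? a[rp + nr * c] : 0;                    // S
          p[5] = (rp < nr && cm >= 0) ? a[rp + nr * cm] : 0;        // SW
          p[6] = (cm >= 0) ? a[r + nr * cm] : 0;                    // W
          p[7] = (rm >= 0 && cm >= 0) ? a[rm + nr * cm] : 0;        // NW
          int b = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (b < 2 || b > 6) continue;
          int trans = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++trans;
          if (trans != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // N*E*S
            if (p[2] * p[4] * p[6] != 0) continue;  // E*S*W
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // N*E*W
            if (p[0] * p[4] * p[6] != 0) continue;  // N*S*W
          }
          kill.push_back(r + nr * c);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) a[kill[k]] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = a[r + nr * c] != 0;
  return out;
}
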