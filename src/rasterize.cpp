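#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixel-center membership: centers sit at integer (x, y), x = column - 1,
// y = row - 1, origin top-left. A center counts as inside when it lies in
// the closed region: even-odd crossing number, with points on a polygon
// edge always included.

static const double EDGE_EPS = 1e-9;

static bool on_segment(double px, double py, double x1, double y1,
                       double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double len2 = dx * dx + dy * dy;
  if (len2 < EDGE_EPS) {
    return std::abs(px - x1) < 1e-7 && std::abs(py - y1) < 1e-7;
  }
  double cross = (px - x1) * dy - (py - y1) * dx;
  if (cross * cross > 1e-14 * len2) return false;
  double t = ((px - x1) * dx + (py - y1) * dy) / len2;
  return t >= -1e-12 && t <= 1.0 + 1e-12;
}

static bool point_in_polygon(double px, double py,
                             const std::vector<double>& xs,
                             const std::vector<double>& ys) {
  int n = xs.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (on_segment(px, py, xs[j], ys[j], xs[i], ys[i])) return true;
    // half-open rule on y avoids double counting at shared vertices
    if ((ys[i] > py) != (ys[j] > py)) {
      double xint = xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j]);
      if (px < xint) inside = !inside;
    }
  }
  return inside;
}

// [[Rcpp::export]]
IntegerMatrix cpp_fill_polygon(NumericVector xs, NumericVector ys,
                               int nrow, int ncol) {
  int n = xs.size();
  std::vector<double> vx(xs.begin(), xs.end());
  std::vector<double> vy(ys.begin(), ys.end());
  IntegerMatrix out(nrow, ncol);
  double xmin = *std::min_element(vx.begin(), vx.end());
  double xmax = *std::max_element(vx.begin(), vx.end());
  double ymin = *std::min_element(vy.begin(), vy.end());
  double ymax = *std::max_element(vy.begin(), vy.end());
  int c0 = std::max(0, (int)std::floor(xmin) - 1);
  int c1 = std::min(ncol - 1, (int)std::ceil(xmax) + 1);
  int r0 = std::max(0, (int)std::floor(ymin) - 1);
  int r1 = std::min(nrow - 1, (int)std::ceil(ymax) + 1);
  if (n < 3) return out;
  for (int r = r0; r <= r1; r++) {
    for (int c = c0; c <= c1; c++) {
      if (point_in_polygon((double)c, (double)r, vx, vy))
        out(r, c) = 1;
    }
  }
  return out;
}

// Rasterize a segment by dense sampling; used for degenerate (collinear) hulls.
// [[Rcpp::export]]
IntegerMatrix cpp_raster_segment(double x0, double y0, double x1, double y1,
                                 int nrow, int ncol) {
  IntegerMatrix out(nrow, ncol);
  double dx = x1 - x0, dy = y1 - y0;
  int nstep = 2 * (int)std::ceil(std::max(std::abs(dx), std::abs(dy))) + 1;
  for (int k = 0; k <= nstep; k++) {
    double t = (double)k / nstep;
    int c = (int)std::lround(x0 + t * dx);
    int r = (int)std::lround(y0 + t * dy);
    if (r >= 0 && r < nrow && c >= 0 && c < ncol) out(r, c) = 1;
  }
  return out;
}

// Connected-component labeling of a {0,1} mask; connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int nn = (connectivity == 8) ? 8 : 4;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      if (mask(r, c) != 0 && lab(r, c) == 0) {
        next++;
        lab(r, c) = next;
        stack.push_back(r + nr * c);
        while (!stack.empty()) {
          int p = stack.back(); stack.pop_back();
          int pr = p % nr, pc = p / nr;
          for (int k = 0; k < nn; k++) {
            int qr = pr + dr[k], qc = pc + dc[k];
            if (qr >= 0 && qr < nr && qc >= 0 && qc < nc &&
                mask(qr, qc) != 0 && lab(qr, qc) == 0) {
              lab(qr, qc) = next;
              stack.push_back(qr + nr * qc);
            }
          }
        }
      }
    }
  }
  return lab;
}
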