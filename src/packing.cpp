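#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int bucket_of(double v, double cell, int nb) {
  int k = (int)std::floor(v / cell);
  if (k < 0) k = 0;
  if (k >= nb) k = nb - 1;
  return k;
}

// Rasterize an inset power diagram (Laguerre-Voronoi) on a pixel grid.
// Pixel centers at ((j+0.5)*px, (i+0.5)*px); labels[i, j], row i = y, col j = x.
// A pixel belongs to fiber k when seed k wins the power distance AND the
// analytic distance from the pixel center to the nearest power bisector
// exceeds inset[k] (endomysial gap + shrinkage erosion). Inset is evaluated
// against the continuous diagram, so gaps narrower than a pixel are still
// honoured in expectation.
// [[Rcpp::export]]
List power_raster_cpp(NumericVector sx, NumericVector sy, NumericVector w,
                      NumericVector inset, int nrow, int ncol, double px,
                      double width_um, double height_um, bool want_labels) {
  const int n = sx.size();
  if (n == 0) stop("no seeds");
  double mean_area = width_um * height_um / n;
  double cell = 2.0 * std::sqrt(mean_area);
  int nbx = std::max(1, (int)std::ceil(width_um / cell));
  int nby = std::max(1, (int)std::ceil(height_um / cell));
  std::vector< std::vector<int> > buck((size_t)nbx * nby);
  for (int i = 0; i < n; ++i)
    buck[(size_t)bucket_of(sy[i], cell, nby) * nbx + bucket_of(sx[i], cell, nbx)].push_back(i);

  IntegerMatrix labels(want_labels ? nrow : 1, want_labels ? ncol : 1);
  NumericVector fiber_px(n), cell_px(n), cx(n), cy(n);
  std::vector<int> cand;
  cand.reserve(64);

  for (int j = 0; j < ncol; ++j) {
    double x = (j + 0.5) * px;
    int bx = bucket_of(x, cell, nbx);
    for (int i = 0; i < nrow; ++i) {
      double y = (i + 0.5) * px;
      int by = bucket_of(y, cell, nby);
      cand.clear();
      int ring = 1;
      while (cand.empty()) {
        for (int byy = std::max(0, by - ring); byy <= std::min(nby - 1, by + ring); ++byy)
          for (int bxx = std::max(0, bx - ring); bxx <= std::min(nbx - 1, bx + ring); ++bxx) {
            const std::vector<int> &b = buck[(size_t)byy * nbx + bxx];
            cand.insert(cand.end(), b.begin(), b.end());
          }
        if (ring > std::max(nbx, nby)) break;
        ++ring;
      }
      int best = -1;
      double bestpd = R_PosInf;
      for (size_t c = 0; c < cand.size(); ++c) {
        int k = cand[c];
        double dx = x - sx[k], dy = y - sy[k];
        double pd = dx * dx + dy * dy - w[k];
        if (pd < bestpd) { bestpd = pd; best = k; }
      }
      cell_px[best] += 1.0;
      cx[best] += x;
      cy[best] += y;
      double margin = R_PosInf;
      for (size_t c = 0; c < cand.size(); ++c) {
        int k = cand[c];
        if (k == best) continue;
        double dx = x - sx[k], dy = y - sy[k];
        double pd = dx * dx + dy * dy - w[k];
        double ex = sx[k] - sx[best], ey = sy[k] - sy[best];
        double d = std::sqrt(ex * ex + ey * ey);
        if (d > 1e-12) {
          double m = (pd - bestpd) / (2.0 * d);
          if (m < margin) margin = m;
        }
      }
      bool is_fiber = margin > inset[best];
      if (is_fiber) fiber_px[best] += 1.0;
      if (want_labels) labels(i, j) = is_fiber ? best + 1 : 0;
    }
  }
  List out = List::create(_["fiber_px"] = fiber_px, _["cell_px"] = cell_px,
                          _["cx"] = cx, _["cy"] = cy);
  if (want_labels) out["labels"] = labels;
  return out;
}

// Per-label raster statistics in one pass: pixel counts, border contact and
// Cauchy-Crofton intercept counts along 4 directions (0, 45, 90, 135 deg).
// Pixels outside the raster count as background, so fibers clipped by the
// field of view still get a closed boundary estimate.
// [[Rcpp::export]]
List label_stats_cpp(IntegerMatrix labels, int n_labels) {
  int nr = labels.nrow(), nc = labels.ncol();
  NumericVector npix(n_labels), n0(n_labels), n90(n_labels), n45(n_labels), n135(n_labels);
  NumericVector sum_x(n_labels), sum_y(n_labels);
  LogicalVector edge(n_labels);

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return labels(i, j);
  };
  auto bump = [&](NumericVector &v, int a, int b) {
    if (a != b) {
      if (a > 0) v[a - 1] += 1.0;
      if (b > 0) v[b - 1] += 1.0;
    }
  };

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int a = labels(i, j);
      if (a > 0) {
        if (a > n_labels) stop("label exceeds n_labels");
        npix[a - 1] += 1.0;
        sum_x[a - 1] += j + 0.5;
        sum_y[a - 1] += i + 0.5;
        if (i == 0 || j == 0 || i == nr - 1 || j == nc - 1) edge[a - 1] = true;
      }
      // horizontal runs (direction 0 deg): neighbour to the right, plus left border
      bump(n0, a, at(i, j + 1));
      if (j == 0) bump(n0, at(i, -1), a);
      // vertical (90 deg)
      bump(n90, a, at(i + 1, j));
      if (i == 0) bump(n90, at(-1, j), a);
      // diagonal down-right (45 deg family)
      bump(n45, a, at(i + 1, j + 1));
      if (i == 0 || j == 0) bump(n45, at(i - 1, j - 1), a);
      // diagonal down-left (135 deg family)
      bump(n135, a, at(i + 1, j - 1));
      if (i == 0 || j == nc - 1) bump(n135, at(i - 1, j + 1), a);
    }
  }
  return List::create(_["npix"] = npix, _["n0"] = n0, _["n90"] = n90,
                      _["n45"] = n45, _["n135"] = n135, _["edge"] = edge,
                      _["sum_x"] = sum_x, _["sum_y"] = sum_y);
}
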