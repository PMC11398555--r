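#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo random walk in a 2D fiber cross-section extruded along z.
// Transverse (x, y) steps are Gaussian with sigma = sqrt(2 D dt) using the
// local compartment diffusivity; the axial coordinate diffuses freely with
// the same local D (the sarcolemma is parallel to z). A step that changes
// the raster label (fiber id or background) is a membrane encounter: it is
// transmitted with probability kappa * sqrt(pi dt / D) and otherwise the
// transverse move is rejected (the walker stays put), which preserves the
// uniform equilibrium distribution.
//
// Phase encoding: qmid[k] is the dephasing wavevector q(t) (rad/um) at the
// midpoint of step k for a unit gradient direction; the per-walker phase
// vector is P = sum_k qmid[k] * dx_k, so the phase along unit direction e is
// dot(e, P). b = int q^2 dt holds for the PGSE profile supplied from R.
//
// Positions are unwrapped for phase/displacement; label lookup wraps
// periodically when wrap = true, otherwise out-of-raster moves are rejected.
// Uses R's RNG (seed with set.seed from R).
// [[Rcpp::export]]
List walk_cpp(IntegerMatrix labels, double px, double D_intra, double D_extra,
              double kappa, double dt, int n_steps, NumericMatrix start,
              NumericVector qmid, bool wrap, int save_every) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const double W = nc * px, H = nr * px;
  const int nw = start.nrow();
  const bool phase_on = qmid.size() > 0;
  if (phase_on && qmid.size() != n_steps) stop("qmid length must equal n_steps");

  auto lab_at = [&](double x, double y) -> int {
    if (wrap) {
      x -= W * std::floor(x / W);
      y -= H * std::floor(y / H);
      if (x >= W) x = 0.0;   // guard against rounding at the seam
      if (y >= H) y = 0.0;
    } else if (x < 0 || x >= W || y < 0 || y >= H) {
      return -1; // outside: impermeable field-of-view edge
    }
    int j = (int)(x / px), i = (int)(y / px);
    if (j >= nc) j = nc - 1;
    if (i >= nr) i = nr - 1;
    return labels(i, j);
  };

  int n_save = (save_every > 0) ? (n_steps / save_every + 1) : 0;
  NumericVector traj(n_save > 0 ? (R_xlen_t)nw * 3 * n_save : 0);
  NumericMatrix P(phase_on ? nw : 1, 3);
  NumericMatrix fin(nw, 3);
  double crossings = 0.0;

  RNGScope scope;
  std::vector<double> X(nw), Y(nw), Z(nw, 0.0);
  std::vector<int> L(nw);
  for (int v = 0; v < nw; ++v) {
    X[v] = start(v, 0);
    Y[v] = start(v, 1);
    L[v] = lab_at(X[v], Y[v]);
    if (L[v] < 0) stop("start position outside raster");
  }
  auto save_pos = [&](int slot) {
    for (int v = 0; v < nw; ++v) {
      traj[(R_xlen_t)slot * nw * 3 + (R_xlen_t)v * 3 + 0] = X[v];
      traj[(R_xlen_t)slot * nw * 3 + (R_xlen_t)v * 3 + 1] = Y[v];
      traj[(R_xlen_t)slot * nw * 3 + (R_xlen_t)v * 3 + 2] = Z[v];
    }
  };
  if (n_save > 0) save_pos(0);

  int slot = 1;
  for (int k = 0; k < n_steps; ++k) {
    double q = phase_on ? qmid[k] : 0.0;
    for (int v = 0; v < nw; ++v) {
      double Dl = (L[v] > 0) ? D_intra : D_extra;
      double s = std::sqrt(2.0 * Dl * dt);
      double dx = s * norm_rand(), dy = s * norm_rand(), dz = s * norm_rand();
      double xn = X[v] + dx, yn = Y[v] + dy;
      int ln = lab_at(xn, yn);
      bool accept;
      if (ln == L[v]) {
        accept = true;
      } else if (ln < 0) {
        accept = false; // field-of-view edge
      } else if (kappa > 0.0 && unif_rand() < kappa * std::sqrt(M_PI * dt / Dl)) {
        accept = true;
        crossings += 1.0;
      } else {
        accept = false;
      }
      if (accept) {
        X[v] = xn; Y[v] = yn; L[v] = ln;
      } else {
        dx = 0.0; dy = 0.0;
      }
      Z[v] += dz; // axial diffusion is never restricted
      if (phase_on) {
        P(v, 0) += q * dx;
        P(v, 1) += q * dy;
        P(v, 2) += q * dz;
      }
    }
    if (n_save > 0 && ((k + 1) % save_every == 0)) {
      if (slot < n_save) save_pos(slot);
      ++slot;
    }
  }
  for (int v = 0; v < nw; ++v) {
    fin(v, 0) = X[v]; fin(v, 1) = Y[v]; fin(v, 2) = Z[v];
  }

  List out = List::create(_["final"] = fin, _["crossings"] = crossings,
                          _["n_walkers"] = nw);
  if (phase_on) out["phase"] = P;
  if (n_save > 0) {
    traj.attr("dim") = IntegerVector::create(3, nw, n_save);
    out["traj"] = traj;
  }
  return out;
}
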