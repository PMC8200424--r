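#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gamma-index DTA search kernels. The evaluated distribution lives on a
// uniform grid (rows = y, cols = x, cell-centre origin, isotropic spacing).
// Dose tolerance dd_abs and distance tolerance dta are absolute. For each
// assessed reference point the gamma functional
//   gamma^2 = dist^2 / dta^2 + (De - Dr)^2 / dd_abs^2
// is minimised over candidate locations of the evaluated distribution.
// Candidates are visited in order of increasing distance so the scan can
// stop as soon as the distance-only term exceeds the current best.

static inline double bilin(const NumericMatrix& v, double fx, double fy,
                           int nx, int ny) {
  // fx, fy: fractional 0-based grid indices, assumed inside [0, n-1]
  int i0 = (int)std::floor(fx); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(fy); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  double tx = fx - i0, ty = fy - j0;
  if (nx == 1) { i0 = 0; tx = 0.0; }
  if (ny == 1) { j0 = 0; ty = 0.0; }
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1);
  return (1 - tx) * (1 - ty) * v(j0, i0) + tx * (1 - ty) * v(j0, i1) +
         (1 - tx) * ty * v(j1, i0) + tx * ty * v(j1, i1);
}

// interpolate = on: candidate positions are ref + shift for shifts on a
// step-spaced disc of radius max_radius, dose bilinearly sampled; shifts
// that land outside the evaluated extent are skipped (never fabricated).
// Returns gamma per point; resolved[i] = 1 when the scan terminated because
// the distance bound exceeded the best (or the shift list was exhausted
// with best <= max_radius/dta), 0 when the radius cap may have bitten.
// [[Rcpp::export]]
List gamma_search_interp(NumericVector ref_x, NumericVector ref_y,
                         NumericVector ref_d, NumericMatrix eval_v,
                         double ev_ox, double ev_oy, double ev_sp,
                         double dd_abs, double dta, double step,
                         double max_radius) {
  const int n = ref_x.size();
  const int nx = eval_v.ncol(), ny = eval_v.nrow();
  const double xmax = ev_ox + (nx - 1) * ev_sp, ymax = ev_oy + (ny - 1) * ev_sp;
  const double eps = 1e-9 * ev_sp;

  // shift disc, sorted by radius
  int m = (int)std::floor(max_radius / step);
  std::vector<double> sdx, sdy, sr2;
  sdx.reserve((2 * m + 1) * (2 * m + 1));
  for (int i = -m; i <= m; ++i) {
    for (int j = -m; j <= m; ++j) {
      double dx = i * step, dy = j * step, r2 = dx * dx + dy * dy;
      if (r2 <= max_radius * max_radius + 1e-12) {
        sdx.push_back(dx); sdy.push_back(dy); sr2.push_back(r2);
      }
    }
  }
  std::vector<int> ord(sdx.size());
  for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int)k;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return sr2[a] < sr2[b]; });

  NumericVector gamma(n);
  IntegerVector resolved(n);
  const double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  for (int p = 0; p < n; ++p) {
    double best = R_PosInf;
    bool done = false;
    for (size_t kk = 0; kk < ord.size(); ++kk) {
      int k = ord[kk];
      double dterm = sr2[k] / dta2;
      if (dterm >= best) { done = true; break; }
      double cx = ref_x[p] + sdx[k], cy = ref_y[p] + sdy[k];
      if (cx < ev_ox - eps || cx > xmax + eps ||
          cy < ev_oy - eps || cy > ymax + eps) continue;
      double fx = (cx - ev_ox) / ev_sp, fy = (cy - ev_oy) / ev_sp;
      if (fx < 0) fx = 0;
      if (fx > nx - 1) fx = nx - 1;
      if (fy < 0) fy = 0;
      if (fy > ny - 1) fy = ny - 1;
      double de = bilin(eval_v, fx, fy, nx, ny);
      double diff = de - ref_d[p];
      double g2 = dterm + diff * diff / dd2;
      if (g2 < best) best = g2;
    }
    gamma[p] = std::sqrt(best);
    resolved[p] = (done || best <= max_radius * max_radius / dta2) ? 1 : 0;
  }
  return List::create(_["gamma"] = gamma, _["resolved"] = resolved);
}

// interpolate = off: candidates are the evaluated grid nodes themselves,
// restricted to distance <= max_radius (pass a non-finite or huge radius for
// an exhaustive exact scan). Scans nodes by expanding index rings so the
// distance bound allows early exit.
// [[Rcpp::export]]
List gamma_search_nodes(NumericVector ref_x, NumericVector ref_y,
                        NumericVector ref_d, NumericMatrix eval_v,
                        double ev_ox, double ev_oy, double ev_sp,
                        double dd_abs, double dta, double max_radius) {
  const int n = ref_x.size();
  const int nx = eval_v.ncol(), ny = eval_v.nrow();
  const double dta2 = dta * dta, dd2 = dd_abs * dd_abs;
  double rad = R_FINITE(max_radius) ? max_radius : R_PosInf;
  const double rad2 = rad * rad * (1 + 1e-12) + 1e-12;

  NumericVector gamma(n);
  IntegerVector resolved(n);
  for (int p = 0; p < n; ++p) {
    // nearest node index to the reference point
    double fx = (ref_x[p] - ev_ox) / ev_sp, fy = (ref_y[p] - ev_oy) / ev_sp;
    int ci = (int)std::lround(fx), cj = (int)std::lround(fy);
    double best = R_PosInf;
    bool any = false, done = false;
    int max_ring = std::max(std::max(ci, nx - 1 - ci) + 1,
                            std::max(cj, ny - 1 - cj) + 1);
    if (R_FINITE(rad)) {
      int cap = (int)std::ceil(rad / ev_sp) + 1;
      if (cap < max_ring) max_ring = cap;
    }
    for (int ring = 0; ring <= max_ring; ++ring) {
      // minimum possible distance from the ref point to any node on this ring
      double ring_min = (ring - 1) > 0 ? ((ring - 1) * ev_sp) : 0.0;
      if (ring_min * ring_min / dta2 >= best) { done = true; break; }
      int ilo = ci - ring, ihi = ci + ring, jlo = cj - ring, jhi = cj + ring;
      for (int j = jlo; j <= jhi; ++j) {
        if (j < 0 || j >= ny) continue;
        bool j_edge = (j == jlo || j == jhi);
        for (int i = ilo; i <= ihi; ++i) {
          if (i < 0 || i >= nx) continue;
          if (!j_edge && i != ilo && i != ihi) continue;  // ring perimeter only
          double dx = ev_ox + i * ev_sp - ref_x[p];
          double dy = ev_oy + j * ev_sp - ref_y[p];
          double r2 = dx * dx + dy * dy;
          if (r2 > rad2) continue;
          any = true;
          double diff = eval_v(j, i) - ref_d[p];
          double g2 = r2 / dta2 + diff * diff / dd2;
          if (g2 < best) best = g2;
        }
      }
    }
    gamma[p] = any ? std::sqrt(best) : NA_REAL;
    resolved[p] = (!any) ? 0 : ((done || best <= rad2 / dta2) ? 1 : 0);
  }
  return List::create(_["gamma"] = gamma, _["resolved"] = resolved);
}
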