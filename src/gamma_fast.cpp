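#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation on a 0-based continuous index; returns NA outside
// the voxel-center extent.
static inline double interp3(const double* v, const int* d,
                             double ix, double iy, double iz) {
  const double tol = 1e-9;
  if (ix < -tol || ix > d[0] - 1 + tol ||
      iy < -tol || iy > d[1] - 1 + tol ||
      iz < -tol || iz > d[2] - 1 + tol)
    return NA_REAL;
  int x0 = (int)std::floor(ix), y0 = (int)std::floor(iy),
      z0 = (int)std::floor(iz);
  x0 = std::min(std::max(x0, 0), d[0] - 2 >= 0 ? d[0] - 2 : 0);
  y0 = std::min(std::max(y0, 0), d[1] - 2 >= 0 ? d[1] - 2 : 0);
  z0 = std::min(std::max(z0, 0), d[2] - 2 >= 0 ? d[2] - 2 : 0);
  double fx = std::min(std::max(ix - x0, 0.0), 1.0);
  double fy = std::min(std::max(iy - y0, 0.0), 1.0);
  double fz = std::min(std::max(iz - z0, 0.0), 1.0);
  int x1 = std::min(x0 + 1, d[0] - 1), y1 = std::min(y0 + 1, d[1] - 1),
      z1 = std::min(z0 + 1, d[2] - 1);
  const long sx = 1, sy = d[0], sz = (long)d[0] * d[1];
  #define V(i, j, k) v[(i) * sx + (j) * sy + (k) * sz]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
  #undef V
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

struct Offset { double dx, dy, dz, d2; };

// Fast gamma engine: for each analyzed reference voxel, minimize
// Gamma^2 = |dr|^2/dta^2 + dD^2/tol^2 over evaluated-dose samples on a
// cubic sub-lattice (step `step` mm) within `searchRadius` mm, visiting
// offsets in order of increasing distance and stopping as soon as the
// distance term alone exceeds the current best.
// [[Rcpp::export(name = ".gammaFastCpp")]]
NumericVector gammaFastCpp(NumericVector refVals, IntegerVector refDim,
                           NumericVector refSpacing, NumericVector refOrigin,
                           NumericVector evalVals, IntegerVector evalDim,
                           NumericVector evalSpacing, NumericVector evalOrigin,
                           LogicalVector analyzed, NumericVector tol,
                           double dta, double searchRadius, double step) {
  const int n = refVals.size();
  NumericVector out(n, NA_REAL);
  const int nk = (int)std::floor(searchRadius / step);
  std::vector<Offset> offs;
  offs.reserve((size_t)(2 * nk + 1) * (2 * nk + 1));
  for (int kx = -nk; kx <= nk; ++kx)
    for (int ky = -nk; ky <= nk; ++ky)
      for (int kz = -nk; kz <= nk; ++kz) {
        double dx = kx * step, dy = ky * step, dz = kz * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= searchRadius * searchRadius)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });
  const double dta2 = dta * dta;
  const double* ev = evalVals.begin();
  const int* ed = evalDim.begin();
  const int rx = refDim[0], ry = refDim[1];
  for (int i = 0; i < n; ++i) {
    if (!analyzed[i]) continue;
    const int iz = i / (rx * ry), iy = (i / rx) % ry, ix = i % rx;
    const double px = refOrigin[0] + ix * refSpacing[0];
    const double py = refOrigin[1] + iy * refSpacing[1];
    const double pz = refOrigin[2] + iz * refSpacing[2];
    const double dr = refVals[i];
    const double ti = tol[i];
    // Gamma^2 at a spatial offset from the reference voxel
    auto gammaAt = [&](double dx, double dy, double dz) -> double {
      double de = interp3(ev, ed,
                          (px + dx - evalOrigin[0]) / evalSpacing[0],
                          (py + dy - evalOrigin[1]) / evalSpacing[1],
                          (pz + dz - evalOrigin[2]) / evalSpacing[2]);
      if (ISNA(de)) return R_PosInf;
      double dd = de - dr;
      double ddTerm;
      if (ti > 0) ddTerm = (dd * dd) / (ti * ti);
      else ddTerm = (dd == 0.0) ? 0.0 : R_PosInf;
      return (dx * dx + dy * dy + dz * dz) / dta2 + ddTerm;
    };
    double best = R_PosInf;
    double bx = 0, by = 0, bz = 0;
    for (const Offset& o : offs) {
      if (o.d2 / dta2 >= best) break;  // sorted: nothing further can win
      double g = gammaAt(o.dx, o.dy, o.dz);
      if (g < best) { best = g; bx = o.dx; by = o.dy; bz = o.dz; }
    }
    // local refinement of the coarse minimum: two shrinking lattice passes
    // around the best offset, resolving the dose-agreement valley far below
    // the coarse sampling step
    if (R_FINITE(best) && best > 0) {
      double radius = step;
      for (int pass = 0; pass < 2; ++pass) {
        double fstep = radius / 5.0;
        double cbx = bx, cby = by, cbz = bz;
        for (int kx = -5; kx <= 5; ++kx)
          for (int ky = -5; ky <= 5; ++ky)
            for (int kz = -5; kz <= 5; ++kz) {
              double dx = cbx + kx * fstep, dy = cby + ky * fstep,
                     dz = cbz + kz * fstep;
              double g = gammaAt(dx, dy, dz);
              if (g < best) { best = g; bx = dx; by = dy; bz = dz; }
            }
        radius = fstep;
      }
    }
    out[i] = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
  }
  return out;
}
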