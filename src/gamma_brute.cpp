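#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Independent brute-force gamma oracle. Deliberately written separately
// from the fast engine: it scans a dense fixed lattice (step `step`,
// normally dta/20) anchored on the evaluated grid and covering its whole
// extent, with no search-radius truncation. The only samples skipped are
// those provably unable to beat the voxel's own zero-offset Gamma value
// gcap (any sample at distance r has Gamma >= r/dta, and gcap is attained
// by an included candidate), so the result is identical to the full scan.

static inline double sample3(const double* v, const int* d,
                             const double* sp, const double* org,
                             double x, double y, double z, bool* ok) {
  double ix = (x - org[0]) / sp[0];
  double iy = (y - org[1]) / sp[1];
  double iz = (z - org[2]) / sp[2];
  const double tol = 1e-9;
  if (ix < -tol || ix > d[0] - 1 + tol || iy < -tol || iy > d[1] - 1 + tol ||
      iz < -tol || iz > d[2] - 1 + tol) {
    *ok = false;
    return 0.0;
  }
  *ok = true;
  int x0 = (int)std::floor(ix); if (x0 > d[0] - 2) x0 = d[0] - 2; if (x0 < 0) x0 = 0;
  int y0 = (int)std::floor(iy); if (y0 > d[1] - 2) y0 = d[1] - 2; if (y0 < 0) y0 = 0;
  int z0 = (int)std::floor(iz); if (z0 > d[2] - 2) z0 = d[2] - 2; if (z0 < 0) z0 = 0;
  double fx = ix - x0; if (fx < 0) fx = 0; if (fx > 1) fx = 1;
  double fy = iy - y0; if (fy < 0) fy = 0; if (fy > 1) fy = 1;
  double fz = iz - z0; if (fz < 0) fz = 0; if (fz > 1) fz = 1;
  int x1 = x0 + 1 < d[0] ? x0 + 1 : d[0] - 1;
  int y1 = y0 + 1 < d[1] ? y0 + 1 : d[1] - 1;
  int z1 = z0 + 1 < d[2] ? z0 + 1 : d[2] - 1;
  const long sy = d[0], sz = (long)d[0] * d[1];
  double v000 = v[x0 + y0 * sy + z0 * sz], v100 = v[x1 + y0 * sy + z0 * sz];
  double v010 = v[x0 + y1 * sy + z0 * sz], v110 = v[x1 + y1 * sy + z0 * sz];
  double v001 = v[x0 + y0 * sy + z1 * sz], v101 = v[x1 + y0 * sy + z1 * sz];
  double v011 = v[x0 + y1 * sy + z1 * sz], v111 = v[x1 + y1 * sy + z1 * sz];
  double c0 = (v000 * (1 - fx) + v100 * fx) * (1 - fy) +
              (v010 * (1 - fx) + v110 * fx) * fy;
  double c1 = (v001 * (1 - fx) + v101 * fx) * (1 - fy) +
              (v011 * (1 - fx) + v111 * fx) * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export(name = ".gammaBruteCpp")]]
NumericVector gammaBruteCpp(NumericVector refVals, IntegerVector refDim,
                            NumericVector refSpacing, NumericVector refOrigin,
                            NumericVector evalVals, IntegerVector evalDim,
                            NumericVector evalSpacing, NumericVector evalOrigin,
                            LogicalVector analyzed, NumericVector tol,
                            double dta, double step) {
  const int n = refVals.size();
  long nAnalyzed = 0;
  for (int i = 0; i < n; ++i) if (analyzed[i]) ++nAnalyzed;
  if (nAnalyzed > 25L * 25L * 25L)
    stop("brute-force gamma guard: instance too large (> 25^3 analyzed voxels)");
  NumericVector out(n, NA_REAL);
  const double* ev = evalVals.begin();
  const int* ed = evalDim.begin();
  const double* esp = evalSpacing.begin();
  const double* eor = evalOrigin.begin();
  // dense lattice node counts covering the evaluated extent
  long nx = (long)std::floor((ed[0] - 1) * esp[0] / step) + 1;
  long ny = (long)std::floor((ed[1] - 1) * esp[1] / step) + 1;
  long nz = (long)std::floor((ed[2] - 1) * esp[2] / step) + 1;
  const double dta2 = dta * dta;
  const int rx = refDim[0], ry = refDim[1];
  for (int i = 0; i < n; ++i) {
    if (!analyzed[i]) continue;
    const int izv = i / (rx * ry), iyv = (i / rx) % ry, ixv = i % rx;
    const double px = refOrigin[0] + ixv * refSpacing[0];
    const double py = refOrigin[1] + iyv * refSpacing[1];
    const double pz = refOrigin[2] + izv * refSpacing[2];
    const double dr = refVals[i];
    const double ti = tol[i];
    bool ok = false;
    double g2cap = R_PosInf;
    double de0 = sample3(ev, ed, esp, eor, px, py, pz, &ok);
    if (ok) {
      double dd0 = de0 - dr;
      if (ti > 0) g2cap = (dd0 * dd0) / (ti * ti);
      else g2cap = (dd0 == 0.0) ? 0.0 : R_PosInf;
    }
    double best = g2cap;  // candidate at the reference position itself
    double rcap2 = R_FINITE(g2cap) ? g2cap * dta2 : R_PosInf;
    // index ranges of lattice nodes that could possibly beat g2cap
    long kx0 = 0, kx1 = nx - 1, ky0 = 0, ky1 = ny - 1, kz0 = 0, kz1 = nz - 1;
    if (R_FINITE(rcap2)) {
      double r = std::sqrt(rcap2);
      kx0 = std::max(0L, (long)std::ceil((px - r - eor[0]) / step));
      kx1 = std::min(nx - 1, (long)std::floor((px + r - eor[0]) / step));
      ky0 = std::max(0L, (long)std::ceil((py - r - eor[1]) / step));
      ky1 = std::min(ny - 1, (long)std::floor((py + r - eor[1]) / step));
      kz0 = std::max(0L, (long)std::ceil((pz - r - eor[2]) / step));
      kz1 = std::min(nz - 1, (long)std::floor((pz + r - eor[2]) / step));
    }
    for (long kz = kz0; kz <= kz1; ++kz) {
      double qz = eor[2] + kz * step;
      double dz2 = (qz - pz) * (qz - pz);
      if (dz2 > rcap2) continue;
      for (long ky = ky0; ky <= ky1; ++ky) {
        double qy = eor[1] + ky * step;
        double dyz2 = dz2 + (qy - py) * (qy - py);
        if (dyz2 > rcap2) continue;
        for (long kx = kx0; kx <= kx1; ++kx) {
          double qx = eor[0] + kx * step;
          double d2 = dyz2 + (qx - px) * (qx - px);
          if (d2 > rcap2) continue;  // Gamma >= sqrt(d2)/dta > gcap: cannot win
          double de = sample3(ev, ed, esp, eor, qx, qy, qz, &ok);
          if (!ok) continue;
          double dd = de - dr;
          double ddTerm;
          if (ti > 0) ddTerm = (dd * dd) / (ti * ti);
          else ddTerm = (dd == 0.0) ? 0.0 : R_PosInf;
          double g = d2 / dta2 + ddTerm;
          if (g < best) best = g;
        }
      }
    }
    out[i] = R_FINITE(best) ? std::sqrt(best) : NA_REAL;
  }
  return out;
}
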