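#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact voxel-traversal line integral of a density array along source->point
// segments (Siddon-style parametric stepping).  Voxel centers sit on the
// lattice origin + (i-1)*spacing; voxel i occupies the half-open interval
// [center - spacing/2, center + spacing/2).  The integral is clipped to the
// grid bounding box, so a source outside the grid contributes nothing until
// the ray enters the box.  Density is in units of the soft-tissue density,
// so the result is a water-equivalent (radiological) path length in cm.

// [[Rcpp::export(name = ".siddonDepth")]]
NumericVector siddonDepth(NumericVector density, IntegerVector dim,
                          NumericVector spacing, NumericVector origin,
                          NumericVector source, NumericMatrix points) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = points.nrow();
  NumericVector out(n);

  const double lo[3] = {origin[0] - 0.5 * spacing[0],
                        origin[1] - 0.5 * spacing[1],
                        origin[2] - 0.5 * spacing[2]};
  const double hi[3] = {origin[0] + (nx - 0.5) * spacing[0],
                        origin[1] + (ny - 0.5) * spacing[1],
                        origin[2] + (nz - 0.5) * spacing[2]};
  const int nplanes[3] = {nx + 1, ny + 1, nz + 1};

  std::vector<double> alphas;
  alphas.reserve(nx + ny + nz + 8);

  for (int p = 0; p < n; ++p) {
    const double S[3] = {source[0], source[1], source[2]};
    const double P[3] = {points(p, 0), points(p, 1), points(p, 2)};
    double d[3];
    double L2 = 0.0;
    for (int a = 0; a < 3; ++a) { d[a] = P[a] - S[a]; L2 += d[a] * d[a]; }
    const double L = std::sqrt(L2);
    if (L <= 0.0) { out[p] = 0.0; continue; }

    // clip [0,1] to the bounding box (slab method)
    double amin = 0.0, amax = 1.0;
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (S[a] < lo[a] || S[a] >= hi[a]) { miss = true; break; }
      } else {
        double a0 = (lo[a] - S[a]) / d[a];
        double a1 = (hi[a] - S[a]) / d[a];
        if (a0 > a1) std::swap(a0, a1);
        if (a0 > amin) amin = a0;
        if (a1 < amax) amax = a1;
      }
    }
    if (miss || amin >= amax) { out[p] = 0.0; continue; }

    // parametric crossings of the voxel boundary planes, per axis, ascending
    alphas.clear();
    alphas.push_back(amin);
    alphas.push_back(amax);
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) continue;
      // plane m (0-based) at lo[a] + m*spacing[a]
      double aEnter = S[a] + amin * d[a];
      double aExit  = S[a] + amax * d[a];
      double pmin = std::min(aEnter, aExit), pmax = std::max(aEnter, aExit);
      int m0 = (int)std::ceil((pmin - lo[a]) / spacing[a] - 1e-9);
      int m1 = (int)std::floor((pmax - lo[a]) / spacing[a] + 1e-9);
      if (m0 < 0) m0 = 0;
      if (m1 > nplanes[a] - 1) m1 = nplanes[a] - 1;
      for (int m = m0; m <= m1; ++m) {
        double al = (lo[a] + m * spacing[a] - S[a]) / d[a];
        if (al > amin && al < amax) alphas.push_back(al);
      }
    }
    std::sort(alphas.begin(), alphas.end());

    double depth = 0.0;
    for (size_t s = 0; s + 1 < alphas.size(); ++s) {
      const double a0 = alphas[s], a1 = alphas[s + 1];
      const double seg = (a1 - a0) * L;
      if (seg <= 0.0) continue;
      const double mid = 0.5 * (a0 + a1);
      int idx[3];
      bool inside = true;
      for (int a = 0; a < 3; ++a) {
        const double pos = S[a] + mid * d[a];
        int i = (int)std::floor((pos - origin[a]) / spacing[a] + 0.5);
        if (i < 0 || i >= (a == 0 ? nx : (a == 1 ? ny : nz))) { inside = false; break; }
        idx[a] = i;
      }
      if (!inside) continue;
      depth += density[idx[0] + nx * (idx[1] + (R_xlen_t)ny * idx[2])] * seg;
    }
    out[p] = depth;
  }
  return out;
}
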