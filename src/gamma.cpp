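#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at fractional 0-based voxel
// coordinates; returns NA outside the grid.
static inline double interp3(const double* v, int nx, int ny, int nz,
                             double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return NA_REAL;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
#define V(i, j, k) v[(i) + (size_t)nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

struct Offset {
  double dx, dy, dz;  // mm
  double dist2_term;  // (|d| / dta)^2
};

// [[Rcpp::export]]
NumericVector gamma_map_cpp(NumericVector ref, NumericVector eval,
                            IntegerVector dims, NumericVector spacing,
                            double dd_frac, double dta, double threshold_frac,
                            bool local, double norm_value, double step_frac,
                            double radius_mult) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* rp = REAL(ref);
  const double* ep = REAL(eval);
  double ref_max = *std::max_element(rp, rp + ref.size());
  double thr = threshold_frac * ref_max;
  double global_tol = dd_frac * (norm_value > 0 ? norm_value : ref_max);

  // Offset lattice at step_frac * dta within radius_mult * dta, sorted by
  // distance so the search can terminate as soon as the distance term alone
  // exceeds the current best gamma^2.
  double step = step_frac * dta;
  double radius = radius_mult * dta;
  int n = (int)std::floor(radius / step);
  std::vector<Offset> offs;
  for (int ix = (nx > 1 ? -n : 0); ix <= (nx > 1 ? n : 0); ix++)
    for (int iy = (ny > 1 ? -n : 0); iy <= (ny > 1 ? n : 0); iy++)
      for (int iz = (nz > 1 ? -n : 0); iz <= (nz > 1 ? n : 0); iz++) {
        double dx = ix * step, dy = iy * step, dz = iz * step;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 > radius * radius + 1e-12) continue;
        offs.push_back({dx, dy, dz, d2 / (dta * dta)});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) {
              return a.dist2_term < b.dist2_term;
            });

  NumericVector out(ref.size(), NA_REAL);
  size_t idx = 0;
  for (int iz = 0; iz < nz; iz++)
    for (int iy = 0; iy < ny; iy++)
      for (int ix = 0; ix < nx; ix++) {
        idx = ix + (size_t)nx * (iy + (size_t)ny * iz);
        double rv = rp[idx];
        if (rv < thr) continue;
        double tol = local ? dd_frac * rv : global_tol;
        if (tol <= 0) tol = 1e-12;
        double best = R_PosInf;
        for (const Offset& o : offs) {
          if (o.dist2_term >= best) break;
          double ev = interp3(ep, nx, ny, nz, ix + o.dx / spacing[0],
                              iy + o.dy / spacing[1], iz + o.dz / spacing[2]);
          if (ISNA(ev)) continue;
          double dd = (ev - rv) / tol;
          double g2 = o.dist2_term + dd * dd;
          if (g2 < best) best = g2;
        }
        out[idx] = std::sqrt(best);
      }
  out.attr("dim") = dims;
  return out;
}

// 26-connected components of equal gray level; returns 1-based labels.
// [[Rcpp::export]]
IntegerVector label_zones_cpp(IntegerVector levels, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t nvox = (size_t)nx * ny * nz;
  IntegerVector labels(nvox, 0);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < nvox; s++) {
    if (labels[s] != 0) continue;
    next++;
    labels[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / ((size_t)nx * ny);
      int lev = levels[cur];
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
              continue;
            size_t q = x + (size_t)nx * (y + (size_t)ny * z);
            if (labels[q] == 0 && levels[q] == lev) {
              labels[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
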