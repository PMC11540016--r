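#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared-distance parabolic lower
// envelope, applied separably along each axis with anisotropic spacing).
// Input: binary mask flattened in column-major (R array) order.
// Output: distance in mm from each TRUE voxel centre to the nearest FALSE
// voxel centre; 0 on FALSE voxels.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h2) {
  // h2 = squared sample spacing along this axis
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = h2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite sentinel: infinity breaks the parabola intersection (INF-INF)
  const double BIG = 1e15;
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  double h2 = spacing[0] * spacing[0];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nx, h2);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  h2 = spacing[1] * spacing[1];
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, d, v, z, ny, h2);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // pass along z
  h2 = spacing[2] * spacing[2];
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nx * ny];
      dt1d(f, d, v, z, nz, h2);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * nx * ny] = d[k];
    }

  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); ++i)
    out[i] = (g[i] >= 1e14) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary 3D mask under 26-connectivity.
// Returns integer labels 1..K in first-encountered order, 0 for background.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((size_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (di == 0 && dj == 0 && dk == 0) continue;
            size_t nb = (size_t)kk * nx * ny + (size_t)jj * nx + ii;
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 3D global gamma index.
// For each evaluated reference voxel, minimises
//   gamma^2 = |p - r|^2 / dta^2 + (Deval(p) - Dref(r))^2 / dd^2
// over a sub-voxel search grid (step = spacing/refine per axis) inside a
// ball of radius ball_mm, with the evaluated dose trilinearly interpolated.
// Search points are visited in order of increasing distance so the loop can
// stop as soon as the spatial term alone exceeds the current minimum.
// Returns gamma per voxel; NA_real_ where the voxel is not evaluated.
// ---------------------------------------------------------------------------

struct Offset { double dx, dy, dz, dist2; };

static inline bool trilinear(const double* ev, int nx, int ny, int nz,
                             double xi, double yi, double zi, double& out) {
  if (xi < 0 || yi < 0 || zi < 0 ||
      xi > nx - 1 || yi > ny - 1 || zi > nz - 1) return false;
  int x0 = (int)std::floor(xi), y0 = (int)std::floor(yi), z0 = (int)std::floor(zi);
  if (x0 == nx - 1) --x0;
  if (y0 == ny - 1) --y0;
  if (z0 == nz - 1) --z0;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  double fx = xi - x0, fy = yi - y0, fz = zi - z0;
  size_t sxy = (size_t)nx * ny;
  const double* p = ev + (size_t)z0 * sxy + (size_t)y0 * nx + x0;
  int sx = (nx > 1) ? 1 : 0;
  int sy = (ny > 1) ? nx : 0;
  size_t sz = (nz > 1) ? sxy : 0;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  out = c0 * (1 - fz) + c1 * fz;
  return true;
}

// [[Rcpp::export(name = ".gamma3d_cpp")]]
NumericVector gamma3d_cpp(NumericVector ref, NumericVector evalv,
                          IntegerVector dims, NumericVector spacing,
                          double dose_tol, double dta, double threshold,
                          LogicalVector evalmask, int refine, double ball_mm) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double dta2 = dta * dta, dd2 = dose_tol * dose_tol;

  // search offsets sorted by distance
  std::vector<Offset> offs;
  int mx = (int)std::ceil(ball_mm * refine / sx);
  int my = (int)std::ceil(ball_mm * refine / sy);
  int mz = (int)std::ceil(ball_mm * refine / sz);
  for (int k = -mz; k <= mz; ++k)
    for (int j = -my; j <= my; ++j)
      for (int i = -mx; i <= mx; ++i) {
        double dx = i * sx / refine, dy = j * sy / refine, dz = k * sz / refine;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= ball_mm * ball_mm + 1e-12)
          offs.push_back({dx, dy, dz, d2});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.dist2 < b.dist2; });

  const double* ev = REAL(evalv);
  NumericVector out(n, NA_REAL);
  bool use_mask = evalmask.size() == (R_xlen_t)n;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t s = (size_t)k * nx * ny + (size_t)j * nx + i;
        double dr = ref[s];
        if (dr < threshold) continue;
        if (use_mask && !evalmask[s]) continue;
        double best = R_PosInf;
        for (const Offset& o : offs) {
          double spatial = o.dist2 / dta2;
          if (spatial >= best) break;  // offsets sorted: nothing better left
          double de;
          if (!trilinear(ev, nx, ny, nz,
                         i + o.dx / sx, j + o.dy / sy, k + o.dz / sz, de))
            continue;
          double diff = de - dr;
          double g2 = spatial + diff * diff / dd2;
          if (g2 < best) best = g2;
        }
        out[s] = std::sqrt(best);
      }
  return out;
}
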