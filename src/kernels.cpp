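#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform.
// f: finite input squared distances at sample positions x (strictly
// increasing); d: output. Positions carry the physical spacing so
// anisotropic voxels work.
static void dt1d(const std::vector<double>& f, const std::vector<double>& x,
                 std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    int p = v[k];
    double s = ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) /
               (2.0 * x[q] - 2.0 * x[p]);
    while (s <= z[k]) {
      --k;
      p = v[k];
      s = ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) /
          (2.0 * x[q] - 2.0 * x[p]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < x[q]) ++k;
    int p = v[k];
    d[q] = (x[q] - x[p]) * (x[q] - x[p]) + f[p];
  }
}

// Exact Euclidean distance (mm) from every foreground voxel to the nearest
// background voxel, with the volume border treated as background. The first
// axis is handled by two linear sweeps (distance to nearest background
// sample along the line, borders included), which leaves every value finite
// for the parabola passes along the remaining axes.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> D((size_t)nx * ny * nz);

  // axis 0: linear sweeps
  {
    const double hx = spacing[0];
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        size_t base = (size_t)k * nx * ny + (size_t)j * nx;
        double run = hx; // distance to virtual background at index -1
        for (int i = 0; i < nx; ++i) {
          if (!fg[base + i]) { run = 0.0; } else { /* keep */ }
          D[base + i] = run;
          run += hx;
        }
        run = hx; // virtual background at index nx
        for (int i = nx - 1; i >= 0; --i) {
          if (!fg[base + i]) { run = 0.0; }
          if (run < D[base + i]) D[base + i] = run;
          run += hx;
        }
        for (int i = 0; i < nx; ++i) D[base + i] *= D[base + i];
      }
    }
  }

  const int nmax = std::max(ny, nz) + 2;
  std::vector<double> f(nmax), x(nmax), d(nmax);

  for (int axis = 1; axis < 3; ++axis) {
    int n = (axis == 1) ? ny : nz;
    double h = spacing[axis];
    size_t stride = (axis == 1) ? (size_t)nx : (size_t)nx * ny;
    int n1 = nx;
    int n2 = (axis == 1) ? nz : ny;
    size_t s1 = 1;
    size_t s2 = (axis == 1) ? (size_t)nx * ny : (size_t)nx;
    for (int j = 0; j < n + 2; ++j) x[j] = (j - 1) * h;
    for (int a = 0; a < n1; ++a) {
      for (int b = 0; b < n2; ++b) {
        size_t base = a * s1 + b * s2;
        f[0] = 0.0; f[n + 1] = 0.0; // volume border is background
        for (int j = 0; j < n; ++j) f[j + 1] = D[base + j * stride];
        dt1d(f, x, d, n + 2);
        for (int j = 0; j < n; ++j) D[base + j * stride] = d[j + 1];
      }
    }
  }
  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < D.size(); ++i) out[i] = std::sqrt(D[i]);
  return out;
}

// 8-connected component of a 2D mask containing a seed pixel (1-based index
// into the column-major nr x nc grid). Returns a logical mask.
// [[Rcpp::export]]
LogicalVector cpp_component8(LogicalVector mask, int nr, int nc, int seed) {
  LogicalVector out(nr * nc, false);
  int s = seed - 1;
  if (s < 0 || s >= nr * nc || !mask[s]) return out;
  std::vector<int> stack;
  stack.push_back(s);
  out[s] = true;
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int r = p % nr, c = p / nr;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int q = cc * nr + rr;
        if (mask[q] && !out[q]) { out[q] = true; stack.push_back(q); }
      }
    }
  }
  return out;
}

// Stamp a tube around a densely sampled centerline into a voxel grid.
// Voxels within radius[i] of the nearest sample i receive label[i]
// (nearest-sample assignment via running minimum distance).
// pts: n x 3 sample coordinates in the volume's voxel frame (mm, axis-aligned,
// origin at voxel (1,1,1) center). Returns an integer label array.
// [[Rcpp::export]]
IntegerVector cpp_stamp_tube(IntegerVector dim, NumericVector spacing,
                             NumericMatrix pts, NumericVector radius,
                             IntegerVector label, double pad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> dmin((size_t)nx * ny * nz,
                           std::numeric_limits<double>::infinity());
  IntegerVector out((size_t)nx * ny * nz, 0);
  const int n = pts.nrow();
  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double r = radius[i] + pad;
    int x0 = std::max(0, (int)std::floor((px - r) / spacing[0]));
    int x1 = std::min(nx - 1, (int)std::ceil((px + r) / spacing[0]));
    int y0 = std::max(0, (int)std::floor((py - r) / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::ceil((py + r) / spacing[1]));
    int z0 = std::max(0, (int)std::floor((pz - r) / spacing[2]));
    int z1 = std::min(nz - 1, (int)std::ceil((pz + r) / spacing[2]));
    for (int k = z0; k <= z1; ++k) {
      double dz = k * spacing[2] - pz;
      for (int j = y0; j <= y1; ++j) {
        double dy = j * spacing[1] - py;
        for (int ii = x0; ii <= x1; ++ii) {
          double dx = ii * spacing[0] - px;
          double d2 = dx * dx + dy * dy + dz * dz;
          size_t idx = (size_t)k * nx * ny + (size_t)j * nx + ii;
          if (d2 < dmin[idx]) {
            dmin[idx] = d2;
            out[idx] = (std::sqrt(d2) <= radius[i]) ? label[i] : 0;
          }
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
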