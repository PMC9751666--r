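#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Column-major index helpers for nx*ny*nz arrays.
static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Reflect an out-of-range coordinate back into [0, n).
static inline int reflect(int c, int n) {
  while (c < 0 || c >= n) {
    if (c < 0) c = -c - 1;
    if (c >= n) c = 2 * n - c - 1;
  }
  return c;
}

// 3D median filter with an odd cubic kernel and reflective edge padding.
// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, IntegerVector dim, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int r = k / 2;
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)k * k * k);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -r; dz <= r; ++dz) {
          int zz = reflect(z + dz, nz);
          for (int dy = -r; dy <= r; ++dy) {
            int yy = reflect(y + dy, ny);
            for (int dx = -r; dx <= r; ++dx) {
              int xx = reflect(x + dx, nx);
              buf.push_back(vol[idx3(xx, yy, zz, nx, ny)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + m - 1, buf.begin() + m);
          med = 0.5 * (med + buf[m - 1]);
        }
        out[idx3(x, y, z, nx, ny)] = med;
      }
  out.attr("dim") = dim;
  return out;
}

static const double DT_INF = 1e20;

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance (in voxel units) from every voxel to the nearest
// TRUE voxel of `feature`.  Voxels with no feature anywhere get a large value.
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector feature, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = feature[i] ? 0.0 : DT_INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[idx3(x, y, zz, nx, ny)];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; ++x) g[idx3(x, y, zz, nx, ny)] = d[x];
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[idx3(x, y, zz, nx, ny)];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; ++y) g[idx3(x, y, zz, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int zz = 0; zz < nz; ++zz) f[zz] = g[idx3(x, y, zz, nx, ny)];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; ++zz) g[idx3(x, y, zz, nx, ny)] = d[zz];
    }

  NumericVector out(n);
  for (size_t i = 0; i < n; ++i)
    out[i] = g[i] >= DT_INF ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}

// Hildebrand-Rueegsegger local thickness by sphere painting: each phase voxel
// receives the diameter (2 * dt) of the largest inscribed sphere covering it.
// `dt` is the distance map of the phase (distance to the complement, voxel
// units); non-phase voxels must carry dt <= 0.  A sphere is skipped only when
// it is entirely contained in a neighbour's sphere (distance-ridge pruning),
// which preserves exactness: containment is transitive and the dominating
// sphere carries a larger diameter.
// [[Rcpp::export]]
NumericVector cpp_thickness_paint(NumericVector dt, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);

  const double eps = 1e-9;
  std::vector<size_t> ridge;
  for (size_t i = 0; i < n; ++i) {
    if (!(dt[i] > 0)) continue;
    int cx = (int)(i % nx);
    int cy = (int)((i / nx) % ny);
    int cz = (int)(i / ((size_t)nx * ny));
    bool dominated = false;
    for (int dz = -1; dz <= 1 && !dominated; ++dz)
      for (int dy = -1; dy <= 1 && !dominated; ++dy)
        for (int dx = -1; dx <= 1 && !dominated; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = cx + dx, yy = cy + dy, zz = cz + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
              zz < 0 || zz >= nz)
            continue;
          double dn = dt[idx3(xx, yy, zz, nx, ny)];
          if (dn >= dt[i] + std::sqrt((double)(dx * dx + dy * dy +
                                               dz * dz)) - eps)
            dominated = true;
        }
    if (!dominated) ridge.push_back(i);
  }

  for (size_t oi = 0; oi < ridge.size(); ++oi) {
    size_t c = ridge[oi];
    double r = dt[c];
    double diam = 2.0 * r;
    int cx = (int)(c % nx);
    int cy = (int)((c / nx) % ny);
    int cz = (int)(c / ((size_t)nx * ny));
    int ri = (int)std::floor(r);
    double r2 = r * r;
    int x0 = std::max(0, cx - ri), x1 = std::min(nx - 1, cx + ri);
    int y0 = std::max(0, cy - ri), y1 = std::min(ny - 1, cy + ri);
    int z0 = std::max(0, cz - ri), z1 = std::min(nz - 1, cz + ri);
    for (int zz = z0; zz <= z1; ++zz) {
      double dz2 = (double)(zz - cz) * (zz - cz);
      for (int yy = y0; yy <= y1; ++yy) {
        double dy2 = (double)(yy - cy) * (yy - cy);
        if (dz2 + dy2 > r2) continue;
        for (int xx = x0; xx <= x1; ++xx) {
          double dd = dz2 + dy2 + (double)(xx - cx) * (xx - cx);
          if (dd > r2) continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (dt[j] > 0 && out[j] < diam) out[j] = diam;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
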