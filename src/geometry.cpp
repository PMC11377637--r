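#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact 1-D squared Euclidean distance transform (lower-envelope algorithm),
// with sites spaced `w` millimetres apart. f holds squared distances from the
// previous pass (R_PosInf where no source). Results written into d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double w) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!R_FINITE(f[q])) continue;
    const double xq = q * w;
    double s = 0.0;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = R_NegInf; z[1] = R_PosInf;
      continue;
    }
    while (true) {
      const int p = v[k];
      const double xp = p * w;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * xq - 2.0 * xp);
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = R_NegInf; z[1] = R_PosInf;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = R_PosInf;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = R_PosInf;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[j + 1] < xq) ++j;
    const double xp = v[j] * w;
    d[q] = (xq - xp) * (xq - xp) + f[v[j]];
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // squared distances, initialised 0 at sources, +Inf elsewhere
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : R_PosInf;

  std::vector<double> f, d;
  // pass along x (fastest-varying index)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = R_FINITE(out[i]) ? std::sqrt(out[i]) : R_PosInf;
  return out;
}

// Connected-component labelling by breadth-first search seeded in scan order,
// so label ids are deterministic: component k contains the k-th foreground
// voxel (column-major order) not reached from an earlier seed.
// [[Rcpp::export(name = ".label_cc_cpp")]]
IntegerVector label_cc_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (connectivity == 6 && ad > 1) continue;
        if (connectivity == 18 && ad > 2) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int cz = (int)(cur / ((R_xlen_t)nx * ny));
      const int rem = (int)(cur % ((R_xlen_t)nx * ny));
      const int cy = rem / nx, cx = rem % nx;
      for (size_t k = 0; k < ox.size(); ++k) {
        const int px = cx + ox[k], py = cy + oy[k], pz = cz + oz[k];
        if (px < 0 || py < 0 || pz < 0 || px >= nx || py >= ny || pz >= nz) continue;
        const R_xlen_t idx = (R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx + px;
        if (mask[idx] && lab[idx] == 0) {
          lab[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  return lab;
}
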