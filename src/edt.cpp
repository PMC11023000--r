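#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Felzenszwalb & Huttenlocher exact 1-D squared distance transform along a
// line of n samples with spacing w (lower envelope of parabolas).
static void dt1d(std::vector<double> &f, std::vector<double> &d, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[k]] == INF) { // first finite parabola
      v[k] = q;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)(q - v[k]) * w;
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact 3-D Euclidean distance transform: for every voxel, the distance (in
// mm, given per-axis spacings) to the nearest feature voxel (feature != 0).
// Returns +Inf everywhere if there is no feature voxel.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector feature, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x-pass (fastest-varying index in column-major order)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
      if (!any) continue;
      f.resize(nx); d.resize(nx);
      dt1d(f, d, spacing[0], v, z);
      f.resize(nmax); d.resize(nmax);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }

  // y-pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
      if (!any) continue;
      f.resize(ny); d.resize(ny);
      dt1d(f, d, spacing[1], v, z);
      f.resize(nmax); d.resize(nmax);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }

  // z-pass
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = out[base + (R_xlen_t)k * sz]; if (f[k] < INF) any = true; }
      if (!any) continue;
      f.resize(nz); d.resize(nz);
      dt1d(f, d, spacing[2], v, z);
      f.resize(nmax); d.resize(nmax);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * sz] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i)
    if (out[i] < INF) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
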