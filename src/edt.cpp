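// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, squared
// distances, separable) with anisotropic voxel spacing: the transform is run
// per axis on samples located at index * spacing. Empty-source voxels start
// at a finite sentinel larger than any achievable squared distance, which
// keeps the parabola arithmetic finite; results are exact whenever the mask
// is non-empty (the empty-mask case is handled by the caller).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// 1D squared-distance transform over samples at positions i*s.
void dt1d(const std::vector<double>& f, int n, double s,
          std::vector<double>& d, std::vector<int>& v,
          std::vector<double>& z, double /*big*/) {
  const double zinf = 1e300;  // beyond any parabola intersection
  int k = 0;
  v[0] = 0;
  z[0] = -zinf;
  z[1] = zinf;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s;
    double inter;
    while (true) {
      double sv = (double)v[k] * s;
      inter = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * (sq - sv));
      if (inter <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = zinf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[k]];
  }
}

} // namespace

// Distance (mm) from every voxel center to the nearest voxel center carrying
// mask == TRUE.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  double extent = nx * spacing[0] + ny * spacing[1] + nz * spacing[2];
  double big = 16.0 * extent * extent + 1.0;  // > any reachable squared distance
  std::vector<double> d(n);
  bool any = false;
  for (R_xlen_t p = 0; p < n; ++p) {
    d[p] = mask[p] ? 0.0 : big;
    if (mask[p]) any = true;
  }
  if (!any) return NumericVector(n, R_PosInf);

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out1(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  auto idx = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = d[idx(i,j,k)];
      dt1d(f, nx, spacing[0], out1, v, z, big);
      for (int i = 0; i < nx; ++i) d[idx(i,j,k)] = out1[i];
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = d[idx(i,j,k)];
      dt1d(f, ny, spacing[1], out1, v, z, big);
      for (int j = 0; j < ny; ++j) d[idx(i,j,k)] = out1[j];
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = d[idx(i,j,k)];
      dt1d(f, nz, spacing[2], out1, v, z, big);
      for (int k = 0; k < nz; ++k) d[idx(i,j,k)] = out1[k];
    }

  NumericVector res(n);
  for (R_xlen_t p = 0; p < n; ++p)
    res[p] = std::sqrt(d[p]);
  return res;
}
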