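// Dense displacement-field machinery shared by the registration, morphing and
// evaluation layers. All fields are stored as R arrays of dimension
// (nx, ny, nz, 3) holding world-unit (mm) vectors on the voxel-center grid of
// their companion image; images are (nx, ny, nz). Conversions between world
// coordinates and (0-based) continuous indices use origin + index * spacing.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double sx, sy, sz;   // spacing (mm)
  double ox, oy, oz;   // world coordinate of voxel (0,0,0) center

  Grid(const IntegerVector& dims, const NumericVector& spacing,
       const NumericVector& origin)
    : nx(dims[0]), ny(dims[1]), nz(dims[2]),
      sx(spacing[0]), sy(spacing[1]), sz(spacing[2]),
      ox(origin[0]), oy(origin[1]), oz(origin[2]) {}

  inline R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
  }
};

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation of one scalar volume at continuous index (fi,fj,fk),
// clamping to the border (replicate padding).
inline double trilinear_clamp(const double* img, const Grid& g,
                              double fi, double fj, double fk) {
  if (fi < 0) fi = 0; if (fi > g.nx - 1) fi = g.nx - 1;
  if (fj < 0) fj = 0; if (fj > g.ny - 1) fj = g.ny - 1;
  if (fk < 0) fk = 0; if (fk > g.nz - 1) fk = g.nz - 1;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj), k0 = (int)std::floor(fk);
  if (i0 > g.nx - 2) i0 = g.nx > 1 ? g.nx - 2 : 0;
  if (j0 > g.ny - 2) j0 = g.ny > 1 ? g.ny - 2 : 0;
  if (k0 > g.nz - 2) k0 = g.nz > 1 ? g.nz - 2 : 0;
  int i1 = std::min(i0 + 1, g.nx - 1), j1 = std::min(j0 + 1, g.ny - 1),
      k1 = std::min(k0 + 1, g.nz - 1);
  double di = fi - i0, dj = fj - j0, dk = fk - k0;
  double c00 = img[g.idx(i0,j0,k0)] * (1-di) + img[g.idx(i1,j0,k0)] * di;
  double c10 = img[g.idx(i0,j1,k0)] * (1-di) + img[g.idx(i1,j1,k0)] * di;
  double c01 = img[g.idx(i0,j0,k1)] * (1-di) + img[g.idx(i1,j0,k1)] * di;
  double c11 = img[g.idx(i0,j1,k1)] * (1-di) + img[g.idx(i1,j1,k1)] * di;
  double c0 = c00 * (1-dj) + c10 * dj;
  double c1 = c01 * (1-dj) + c11 * dj;
  return c0 * (1-dk) + c1 * dk;
}

// Trilinear interpolation returning 0 outside the grid (background).
inline double trilinear_zero(const double* img, const Grid& g,
                             double fi, double fj, double fk) {
  if (fi < -1 || fi > g.nx || fj < -1 || fj > g.ny || fk < -1 || fk > g.nz)
    return 0.0;
  int i0 = (int)std::floor(fi), j0 = (int)std::floor(fj), k0 = (int)std::floor(fk);
  double di = fi - i0, dj = fj - j0, dk = fk - k0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int k = k0 + dz; if (k < 0 || k >= g.nz) continue;
    double wz = dz ? dk : 1 - dk;
    for (int dy = 0; dy <= 1; ++dy) {
      int j = j0 + dy; if (j < 0 || j >= g.ny) continue;
      double wy = dy ? dj : 1 - dj;
      for (int dx = 0; dx <= 1; ++dx) {
        int i = i0 + dx; if (i < 0 || i >= g.nx) continue;
        double wx = dx ? di : 1 - di;
        out += img[g.idx(i,j,k)] * wx * wy * wz;
      }
    }
  }
  return out;
}

// Sample a 3-component field (clamped) at continuous index coordinates.
inline void sample_field_clamp(const double* u, const Grid& g,
                               double fi, double fj, double fk, double out[3]) {
  R_xlen_t n = g.n();
  out[0] = trilinear_clamp(u,         g, fi, fj, fk);
  out[1] = trilinear_clamp(u + n,     g, fi, fj, fk);
  out[2] = trilinear_clamp(u + 2 * n, g, fi, fj, fk);
}

// Separable Gaussian smoothing along one axis, replicate border. sigma in
// voxels of that axis; no-op when sigma <= 0.
void smooth_axis(std::vector<double>& a, const Grid& g, int axis, double sigma) {
  if (sigma <= 0) return;
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    k[t + radius] = std::exp(-(double)t * t / s2);
    sum += k[t + radius];
  }
  for (double& w : k) w /= sum;

  int n_axis = axis == 0 ? g.nx : (axis == 1 ? g.ny : g.nz);
  std::vector<double> line(n_axis), out(n_axis);
  int nu = axis == 0 ? g.ny : g.nx;
  int nv = axis == 2 ? g.ny : g.nz;
  for (int v = 0; v < nv; ++v) {
    for (int uu = 0; uu < nu; ++uu) {
      for (int t = 0; t < n_axis; ++t) {
        int i = axis == 0 ? t : uu, j = axis == 1 ? t : (axis == 0 ? uu : uu),
            kk = axis == 2 ? t : v;
        if (axis == 1) { i = uu; j = t; kk = v; }
        if (axis == 0) { i = t; j = uu; kk = v; }
        if (axis == 2) { i = uu; j = v; kk = t; }
        line[t] = a[g.idx(i, j, kk)];
      }
      for (int t = 0; t < n_axis; ++t) {
        double acc = 0.0;
        for (int w = -radius; w <= radius; ++w)
          acc += k[w + radius] * line[clampi(t + w, 0, n_axis - 1)];
        out[t] = acc;
      }
      for (int t = 0; t < n_axis; ++t) {
        int i = 0, j = 0, kk = 0;
        if (axis == 0) { i = t; j = uu; kk = v; }
        if (axis == 1) { i = uu; j = t; kk = v; }
        if (axis == 2) { i = uu; j = v; kk = t; }
        a[g.idx(i, j, kk)] = out[t];
      }
    }
  }
}

void smooth3(std::vector<double>& a, const Grid& g,
             double sx, double sy, double sz) {
  smooth_axis(a, g, 0, sx);
  smooth_axis(a, g, 1, sy);
  smooth_axis(a, g, 2, sz);
}

// In-place field composition: r(x) = d(x) + u(x + d(x)); u sampled clamped.
void compose_into(const std::vector<double>& d, const std::vector<double>& u,
                  const Grid& g, std::vector<double>& r) {
  R_xlen_t n = g.n();
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        R_xlen_t p = g.idx(i, j, k);
        double fi = i + d[p] / g.sx;
        double fj = j + d[p + n] / g.sy;
        double fk = k + d[p + 2 * n] / g.sz;
        double uv[3];
        sample_field_clamp(u.data(), g, fi, fj, fk, uv);
        r[p]         = d[p]         + uv[0];
        r[p + n]     = d[p + n]     + uv[1];
        r[p + 2 * n] = d[p + 2 * n] + uv[2];
      }
}

// Exponential of a (small) stationary velocity step by scaling and squaring.
void exp_field(std::vector<double>& d, const Grid& g) {
  R_xlen_t n = g.n();
  double mx = 0.0;
  for (R_xlen_t p = 0; p < n; ++p) {
    double vi = d[p] / g.sx, vj = d[p + n] / g.sy, vk = d[p + 2 * n] / g.sz;
    double m = std::sqrt(vi * vi + vj * vj + vk * vk);
    if (m > mx) mx = m;
  }
  int nsq = 0;
  if (mx > 0.5) nsq = (int)std::ceil(std::log2(mx / 0.5));
  if (nsq > 30) nsq = 30;
  double scale = std::pow(2.0, -nsq);
  for (double& v : d) v *= scale;
  std::vector<double> tmp(d.size());
  for (int s = 0; s < nsq; ++s) {
    compose_into(d, d, g, tmp);
    d.swap(tmp);
  }
}

// Central-difference gradient of a scalar volume (one-sided at borders),
// in 1/mm units.
void gradient3(const std::vector<double>& a, const Grid& g,
               std::vector<double>& gx, std::vector<double>& gy,
               std::vector<double>& gz) {
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        R_xlen_t p = g.idx(i, j, k);
        int im = std::max(i - 1, 0), ip = std::min(i + 1, g.nx - 1);
        int jm = std::max(j - 1, 0), jp = std::min(j + 1, g.ny - 1);
        int km = std::max(k - 1, 0), kp = std::min(k + 1, g.nz - 1);
        gx[p] = (a[g.idx(ip,j,k)] - a[g.idx(im,j,k)]) / ((ip - im) * g.sx);
        gy[p] = (a[g.idx(i,jp,k)] - a[g.idx(i,jm,k)]) / ((jp - jm) * g.sy);
        gz[p] = (a[g.idx(i,j,kp)] - a[g.idx(i,j,km)]) / ((kp - km) * g.sz);
      }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_sample_field(NumericVector field, IntegerVector dims,
                               NumericVector spacing, NumericVector origin,
                               NumericMatrix points, int outside_policy) {
  Grid g(dims, spacing, origin);
  R_xlen_t n = g.n();
  const double* u = REAL(field);
  int np = points.nrow();
  NumericMatrix out(np, 3);
  int n_outside = 0;
  std::vector<int> outside_idx;
  for (int p = 0; p < np; ++p) {
    double fi = (points(p, 0) - g.ox) / g.sx;
    double fj = (points(p, 1) - g.oy) / g.sy;
    double fk = (points(p, 2) - g.oz) / g.sz;
    bool outside = fi < 0 || fi > g.nx - 1 || fj < 0 || fj > g.ny - 1 ||
                   fk < 0 || fk > g.nz - 1;
    if (outside) {
      ++n_outside;
      if (outside_policy == 2 && (int)outside_idx.size() < 20)
        outside_idx.push_back(p + 1);
      if (outside_policy == 1) {  // zero
        out(p, 0) = out(p, 1) = out(p, 2) = 0.0;
        continue;
      }
    }
    double uv[3];
    sample_field_clamp(u, g, fi, fj, fk, uv);
    out(p, 0) = uv[0]; out(p, 1) = uv[1]; out(p, 2) = uv[2];
  }
  if (outside_policy == 2 && n_outside > 0) {
    std::string msg = "points outside field grid (first indices:";
    for (int ix : outside_idx) msg += " " + std::to_string(ix);
    msg += "), n=" + std::to_string(n_outside);
    stop(msg);
  }
  out.attr("outside_count") = n_outside;
  (void)n;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_smooth_volume(NumericVector a, IntegerVector dims,
                                NumericVector sigma_vox, int ncomp) {
  Grid g(dims, NumericVector::create(1, 1, 1), NumericVector::create(0, 0, 0));
  R_xlen_t n = g.n();
  NumericVector out(clone(a));
  std::vector<double> buf(n);
  for (int c = 0; c < ncomp; ++c) {
    std::copy(out.begin() + c * n, out.begin() + (c + 1) * n, buf.begin());
    smooth3(buf, g, sigma_vox[0], sigma_vox[1], sigma_vox[2]);
    std::copy(buf.begin(), buf.end(), out.begin() + c * n);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_compose_fields(NumericVector d, NumericVector u,
                                 IntegerVector dims, NumericVector spacing) {
  Grid g(dims, spacing, NumericVector::create(0, 0, 0));
  R_xlen_t n3 = g.n() * 3;
  std::vector<double> dv(REAL(d), REAL(d) + n3), uv(REAL(u), REAL(u) + n3),
      r(n3);
  compose_into(dv, uv, g, r);
  return NumericVector(r.begin(), r.end());
}

// [[Rcpp::export]]
NumericVector cpp_exp_field(NumericVector delta, IntegerVector dims,
                            NumericVector spacing) {
  Grid g(dims, spacing, NumericVector::create(0, 0, 0));
  std::vector<double> d(REAL(delta), REAL(delta) + g.n() * 3);
  exp_field(d, g);
  return NumericVector(d.begin(), d.end());
}

// Warp a scalar image through a displacement field on the same grid:
// out(x) = img(x + field(x)). interp 0 = nearest neighbour, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_warp_scalar(NumericVector img, IntegerVector dims,
                              NumericVector spacing, NumericVector field,
                              int interp, double outside_value) {
  Grid g(dims, spacing, NumericVector::create(0, 0, 0));
  R_xlen_t n = g.n();
  const double* a = REAL(img);
  const double* u = REAL(field);
  NumericVector out(n);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        R_xlen_t p = g.idx(i, j, k);
        double fi = i + u[p] / g.sx;
        double fj = j + u[p + n] / g.sy;
        double fk = k + u[p + 2 * n] / g.sz;
        if (interp == 0) {
          int ii = (int)std::lround(fi), jj = (int)std::lround(fj),
              kk = (int)std::lround(fk);
          if (ii < 0 || ii >= g.nx || jj < 0 || jj >= g.ny || kk < 0 ||
              kk >= g.nz)
            out[p] = outside_value;
          else
            out[p] = a[g.idx(ii, jj, kk)];
        } else {
          if (fi < -1 || fi > g.nx || fj < -1 || fj > g.ny || fk < -1 ||
              fk > g.nz)
            out[p] = outside_value;
          else
            out[p] = trilinear_zero(a, g, fi, fj, fk);
        }
      }
  return out;
}

// Resample an image through an affine map: out(x) = img(A x + t), where x is
// a world coordinate of the output grid and A x + t a world coordinate of the
// input grid. interp 0 = nearest, 1 = trilinear (zero outside).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector img, IntegerVector dims,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix A, NumericVector t,
                                  IntegerVector out_dims,
                                  NumericVector out_spacing,
                                  NumericVector out_origin, int interp,
                                  double outside_value) {
  Grid gi(dims, spacing, origin);
  Grid go(out_dims, out_spacing, out_origin);
  const double* a = REAL(img);
  NumericVector out(go.n());
  for (int k = 0; k < go.nz; ++k)
    for (int j = 0; j < go.ny; ++j)
      for (int i = 0; i < go.nx; ++i) {
        double wx = go.ox + i * go.sx, wy = go.oy + j * go.sy,
               wz = go.oz + k * go.sz;
        double px = A(0,0)*wx + A(0,1)*wy + A(0,2)*wz + t[0];
        double py = A(1,0)*wx + A(1,1)*wy + A(1,2)*wz + t[1];
        double pz = A(2,0)*wx + A(2,1)*wy + A(2,2)*wz + t[2];
        double fi = (px - gi.ox) / gi.sx, fj = (py - gi.oy) / gi.sy,
               fk = (pz - gi.oz) / gi.sz;
        R_xlen_t p = go.idx(i, j, k);
        if (interp == 0) {
          int ii = (int)std::lround(fi), jj = (int)std::lround(fj),
              kk = (int)std::lround(fk);
          if (ii < 0 || ii >= gi.nx || jj < 0 || jj >= gi.ny || kk < 0 ||
              kk >= gi.nz)
            out[p] = outside_value;
          else
            out[p] = a[gi.idx(ii, jj, kk)];
        } else {
          if (fi < -1 || fi > gi.nx || fj < -1 || fj > gi.ny || fk < -1 ||
              fk > gi.nz)
            out[p] = outside_value;
          else
            out[p] = trilinear_zero(a, gi, fi, fj, fk);
        }
      }
  return out;
}

// One pyramid level of diffeomorphic Demons. fixed/moving are float volumes
// on a common grid; u_init the (possibly upsampled) field in mm. Each
// iteration computes symmetric demon forces, smooths the update (fluid
// sigma), exponentiates it by scaling-and-squaring, composes it into the
// accumulated field and smooths that field (diffusion sigma = smooth factor).
// [[Rcpp::export]]
List cpp_demons_level(NumericVector fixed, NumericVector moving,
                      IntegerVector dims, NumericVector spacing,
                      NumericVector u_init, int iterations,
                      double sigma_diffusion_vox, double sigma_fluid_vox,
                      double max_step_vox, double tol_vox) {
  Grid g(dims, spacing, NumericVector::create(0, 0, 0));
  R_xlen_t n = g.n();
  std::vector<double> f(REAL(fixed), REAL(fixed) + n);
  const double* m = REAL(moving);
  std::vector<double> u(REAL(u_init), REAL(u_init) + 3 * n);
  std::vector<double> mw(n), gfx(n), gfy(n), gfz(n), gmx(n), gmy(n), gmz(n);
  std::vector<double> del(3 * n), tmp(3 * n);
  gradient3(f, g, gfx, gfy, gfz);

  double K = (spacing[0] * spacing[0] + spacing[1] * spacing[1] +
              spacing[2] * spacing[2]) / 3.0;
  double min_sp = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  double max_step = max_step_vox * min_sp;
  std::vector<double> mean_updates;
  int iters_run = 0;

  for (int it = 0; it < iterations; ++it) {
    // moving warped by current field
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          R_xlen_t p = g.idx(i, j, k);
          double fi = i + u[p] / g.sx;
          double fj = j + u[p + n] / g.sy;
          double fk = k + u[p + 2 * n] / g.sz;
          mw[p] = (fi < -1 || fi > g.nx || fj < -1 || fj > g.ny || fk < -1 ||
                   fk > g.nz)
                      ? 0.0
                      : trilinear_zero(m, g, fi, fj, fk);
        }
    gradient3(mw, g, gmx, gmy, gmz);

    double upd_sum = 0.0;
    for (R_xlen_t p = 0; p < n; ++p) {
      double diff = f[p] - mw[p];
      double jx = 0.5 * (gfx[p] + gmx[p]);
      double jy = 0.5 * (gfy[p] + gmy[p]);
      double jz = 0.5 * (gfz[p] + gmz[p]);
      double den = jx * jx + jy * jy + jz * jz + diff * diff / K;
      double s = den > 1e-12 ? diff / den : 0.0;
      double dx = s * jx, dy = s * jy, dz = s * jz;
      double mag = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (mag > max_step) {
        double r = max_step / mag;
        dx *= r; dy *= r; dz *= r;
        mag = max_step;
      }
      del[p] = dx; del[p + n] = dy; del[p + 2 * n] = dz;
      upd_sum += mag;
    }
    double mean_upd_vox = upd_sum / (double)n / min_sp;
    mean_updates.push_back(mean_upd_vox);
    ++iters_run;

    if (sigma_fluid_vox > 0) {
      for (int c = 0; c < 3; ++c) {
        std::vector<double> comp(del.begin() + c * n, del.begin() + (c + 1) * n);
        smooth3(comp, g, sigma_fluid_vox, sigma_fluid_vox, sigma_fluid_vox);
        std::copy(comp.begin(), comp.end(), del.begin() + c * n);
      }
    }
    exp_field(del, g);
    compose_into(del, u, g, tmp);
    u.swap(tmp);
    if (sigma_diffusion_vox > 0) {
      for (int c = 0; c < 3; ++c) {
        std::vector<double> comp(u.begin() + c * n, u.begin() + (c + 1) * n);
        smooth3(comp, g, sigma_diffusion_vox, sigma_diffusion_vox,
                sigma_diffusion_vox);
        std::copy(comp.begin(), comp.end(), u.begin() + c * n);
      }
    }
    for (double v : u)
      if (!std::isfinite(v))
        stop("demons update diverged (non-finite field) at iteration %d", it + 1);
    if (mean_upd_vox < tol_vox) break;
  }

  return List::create(_["u"] = NumericVector(u.begin(), u.end()),
                      _["mean_updates"] = NumericVector(mean_updates.begin(),
                                                        mean_updates.end()),
                      _["iterations"] = iters_run);
}

// Fixed-point inversion v <- -u(x + v(x)). Returns the inverse field plus the
// residual statistics max/mean |u(x+v(x)) + v(x)| in mm.
// [[Rcpp::export]]
List cpp_invert_field(NumericVector field, IntegerVector dims,
                      NumericVector spacing, double tol_mm, int max_iter) {
  Grid g(dims, spacing, NumericVector::create(0, 0, 0));
  R_xlen_t n = g.n();
  const double* u = REAL(field);
  std::vector<double> v(3 * n, 0.0), vn(3 * n);
  int it = 0;
  for (; it < max_iter; ++it) {
    double max_change = 0.0;
    for (int k = 0; k < g.nz; ++k)
      for (int j = 0; j < g.ny; ++j)
        for (int i = 0; i < g.nx; ++i) {
          R_xlen_t p = g.idx(i, j, k);
          double fi = i + v[p] / g.sx;
          double fj = j + v[p + n] / g.sy;
          double fk = k + v[p + 2 * n] / g.sz;
          double uv[3];
          sample_field_clamp(u, g, fi, fj, fk, uv);
          vn[p] = -uv[0]; vn[p + n] = -uv[1]; vn[p + 2 * n] = -uv[2];
          double ch = std::max(std::fabs(vn[p] - v[p]),
                               std::max(std::fabs(vn[p + n] - v[p + n]),
                                        std::fabs(vn[p + 2 * n] - v[p + 2 * n])));
          if (ch > max_change) max_change = ch;
        }
    v.swap(vn);
    if (max_change < tol_mm) { ++it; break; }
  }
  // residual of the found inverse
  double res_sum = 0.0, res_max = 0.0;
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        R_xlen_t p = g.idx(i, j, k);
        double fi = i + v[p] / g.sx;
        double fj = j + v[p + n] / g.sy;
        double fk = k + v[p + 2 * n] / g.sz;
        double uv[3];
        sample_field_clamp(u, g, fi, fj, fk, uv);
        double rx = uv[0] + v[p], ry = uv[1] + v[p + n],
               rz = uv[2] + v[p + 2 * n];
        double r = std::sqrt(rx * rx + ry * ry + rz * rz);
        res_sum += r;
        if (r > res_max) res_max = r;
      }
  return List::create(_["v"] = NumericVector(v.begin(), v.end()),
                      _["iterations"] = it,
                      _["residual_mean"] = res_sum / (double)n,
                      _["residual_max"] = res_max);
}

// Determinant of the Jacobian of the warp x -> x + u(x) at every voxel
// (one-sided differences at borders).
// [[Rcpp::export]]
NumericVector cpp_warp_jacobian(NumericVector field, IntegerVector dims,
                                NumericVector spacing) {
  Grid g(dims, spacing, NumericVector::create(0, 0, 0));
  R_xlen_t n = g.n();
  const double* u = REAL(field);
  NumericVector out(n);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        int im = std::max(i - 1, 0), ip = std::min(i + 1, g.nx - 1);
        int jm = std::max(j - 1, 0), jp = std::min(j + 1, g.ny - 1);
        int km = std::max(k - 1, 0), kp = std::min(k + 1, g.nz - 1);
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* uc = u + (R_xlen_t)c * n;
          J[c][0] = (uc[g.idx(ip,j,k)] - uc[g.idx(im,j,k)]) / ((ip - im) * g.sx);
          J[c][1] = (uc[g.idx(i,jp,k)] - uc[g.idx(i,jm,k)]) / ((jp - jm) * g.sy);
          J[c][2] = (uc[g.idx(i,j,kp)] - uc[g.idx(i,j,km)]) / ((kp - km) * g.sz);
          J[c][c] += 1.0;
        }
        out[g.idx(i,j,k)] =
            J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
            J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
            J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
      }
  return out;
}

// Block-mean downsampling by an integer factor (partial edge blocks averaged
// over available voxels).
// [[Rcpp::export]]
NumericVector cpp_downsample_mean(NumericVector img, IntegerVector dims,
                                  int factor) {
  Grid g(dims, NumericVector::create(1, 1, 1), NumericVector::create(0, 0, 0));
  int nx = (dims[0] + factor - 1) / factor;
  int ny = (dims[1] + factor - 1) / factor;
  int nz = (dims[2] + factor - 1) / factor;
  const double* a = REAL(img);
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0; int c = 0;
        for (int dk = 0; dk < factor; ++dk) {
          int kk = k * factor + dk; if (kk >= dims[2]) break;
          for (int dj = 0; dj < factor; ++dj) {
            int jj = j * factor + dj; if (jj >= dims[1]) break;
            for (int di = 0; di < factor; ++di) {
              int ii = i * factor + di; if (ii >= dims[0]) break;
              s += a[g.idx(ii, jj, kk)]; ++c;
            }
          }
        }
        out[(R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] =
            s / c;
      }
  out.attr("newdims") = IntegerVector::create(nx, ny, nz);
  return out;
}
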