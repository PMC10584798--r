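// Computational core: rotation-based attenuated parallel-beam projector with
// distance-dependent Gaussian collimator response (incremental-blur
// accumulation), its exact adjoint, the relative difference prior, and small
// image operators (3D Gaussian blur, 3D convolution, trilinear resampling,
// 26-connected component extraction).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double FWHM_TO_SIGMA = 1.0 / 2.3548200450309493;

// ---------------------------------------------------------------- blurring

static vec gauss_kernel(double sigma_pix) {
  int r = (int)std::ceil(3.5 * sigma_pix);
  if (r < 1) r = 1;
  vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)i * (double)i / (sigma_pix * sigma_pix));
  k /= accu(k);
  return k;
}

// 1D convolution with zero padding along columns (down each column)
static void conv_cols(mat& M, const vec& k) {
  int r = ((int)k.n_elem - 1) / 2;
  int n = M.n_rows;
  mat out(M.n_rows, M.n_cols, fill::zeros);
  for (uword j = 0; j < M.n_cols; ++j) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
      for (int t = lo; t <= hi; ++t) s += M(t, j) * k(i - t + r);
      out(i, j) = s;
    }
  }
  M = out;
}

// separable 2D Gaussian blur (zero padding); sigmas in pixel units
static void blur2d(mat& M, double sig_u, double sig_v) {
  if (sig_u > 1e-8) {
    vec k = gauss_kernel(sig_u);
    conv_cols(M, k);
  }
  if (sig_v > 1e-8) {
    vec k = gauss_kernel(sig_v);
    inplace_trans(M);
    conv_cols(M, k);
    inplace_trans(M);
  }
}

// ---------------------------------------------------------------- rotation

// Bilinear in-plane rotation, precompiled into linear-index gather tables.
// Interior targets (all four source neighbours valid) take a branch-free
// fast path; border targets carry explicit per-neighbour validity flags.
struct RotMap {
  int nx, ny;
  std::vector<int> ti, si;               // interior: target / source base
  std::vector<double> w00, w10, w01, w11;
  std::vector<int> bt;                   // border: target linear index
  std::vector<std::array<int, 4>> bs;    // source linear indices (-1 invalid)
  std::vector<std::array<double, 4>> bw;
};

static RotMap make_rotmap(int nx, int ny, double theta) {
  RotMap rm;
  rm.nx = nx; rm.ny = ny;
  double c = std::cos(theta), s = std::sin(theta);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double xs = cx + c * (i - cx) - s * (j - cy);
      double ys = cy + s * (i - cx) + c * (j - cy);
      int ii = (int)std::floor(xs), jj = (int)std::floor(ys);
      if (ii < -1 || ii > nx - 1 || jj < -1 || jj > ny - 1) continue;
      double fx = xs - ii, fy = ys - jj;
      double w[4] = {(1 - fx) * (1 - fy), fx * (1 - fy),
                     (1 - fx) * fy, fx * fy};
      int t = i + nx * j;
      if (ii >= 0 && jj >= 0 && ii + 1 < nx && jj + 1 < ny) {
        rm.ti.push_back(t);
        rm.si.push_back(ii + nx * jj);
        rm.w00.push_back(w[0]); rm.w10.push_back(w[1]);
        rm.w01.push_back(w[2]); rm.w11.push_back(w[3]);
      } else {
        std::array<int, 4> src;
        int di[4] = {0, 1, 0, 1}, dj[4] = {0, 0, 1, 1};
        for (int n = 0; n < 4; ++n) {
          int a = ii + di[n], b = jj + dj[n];
          src[n] = (a >= 0 && a < nx && b >= 0 && b < ny) ? a + nx * b : -1;
        }
        rm.bt.push_back(t);
        rm.bs.push_back(src);
        rm.bw.push_back({w[0], w[1], w[2], w[3]});
      }
    }
  }
  return rm;
}

static void rotate_cube(const cube& v, const RotMap& rm, cube& out) {
  int nz = v.n_slices;
  size_t nin = rm.ti.size(), nb = rm.bt.size();
  out.zeros();
  for (int k = 0; k < nz; ++k) {
    const double* p = v.slice_memptr(k);
    double* o = out.slice_memptr(k);
    int nx = rm.nx;
    for (size_t m = 0; m < nin; ++m) {
      const double* q = p + rm.si[m];
      o[rm.ti[m]] = rm.w00[m] * q[0] + rm.w10[m] * q[1] +
                    rm.w01[m] * q[nx] + rm.w11[m] * q[nx + 1];
    }
    for (size_t m = 0; m < nb; ++m) {
      double s = 0.0;
      for (int n = 0; n < 4; ++n)
        if (rm.bs[m][n] >= 0) s += rm.bw[m][n] * p[rm.bs[m][n]];
      o[rm.bt[m]] = s;
    }
  }
}

// exact adjoint of rotate_cube: scatter-add with the same weights
static void rotate_cube_adj(const cube& v, const RotMap& rm, cube& out) {
  int nz = v.n_slices;
  size_t nin = rm.ti.size(), nb = rm.bt.size();
  for (int k = 0; k < nz; ++k) {
    const double* p = v.slice_memptr(k);
    double* o = out.slice_memptr(k);
    int nx = rm.nx;
    for (size_t m = 0; m < nin; ++m) {
      double val = p[rm.ti[m]];
      if (val == 0.0) continue;
      double* q = o + rm.si[m];
      q[0] += rm.w00[m] * val;
      q[1] += rm.w10[m] * val;
      q[nx] += rm.w01[m] * val;
      q[nx + 1] += rm.w11[m] * val;
    }
    for (size_t m = 0; m < nb; ++m) {
      double val = p[rm.bt[m]];
      if (val == 0.0) continue;
      for (int n = 0; n < 4; ++n)
        if (rm.bs[m][n] >= 0) o[rm.bs[m][n]] += rm.bw[m][n] * val;
    }
  }
}

// --------------------------------------------------------- depth-psf model

// squared Gaussian sigma (mm^2) of the collimator-detector response at
// distance d (mm) from the collimator face
static double sigma2_at(double d, double fwhm_int, double off, double slope) {
  if (d < 0) d = 0;
  double g = off + slope * d;
  double f2 = fwhm_int * fwhm_int + g * g;
  return f2 * FWHM_TO_SIGMA * FWHM_TO_SIGMA;
}

// incremental-blur schedule: sig2_before(y) is the variance increment applied
// to the running accumulator before plane y is added (planes processed from
// the far side y = 0 toward the detector at y = ny-1); sig2_final is applied
// after the last plane.  Increments are flushed lazily once they exceed
// flush = (0.25 * pitch)^2 so each plane's total applied variance is within
// flush of its nominal sigma2_at value.
static void blur_schedule(int ny, double dy, double det_radius,
                          double fwhm_int, double off, double slope,
                          double pitch, vec& sig2_before, double& sig2_final) {
  sig2_before.zeros(ny);
  double cy = 0.5 * (ny - 1);
  vec s2(ny);
  for (int y = 0; y < ny; ++y)
    s2(y) = sigma2_at(det_radius - (y - cy) * dy, fwhm_int, off, slope);
  double flush = 0.0625 * pitch * pitch;
  double pending = 0.0;
  for (int y = 1; y < ny; ++y) {
    pending += s2(y - 1) - s2(y);
    if (pending >= flush) {
      sig2_before(y) = pending;
      pending = 0.0;
    }
  }
  sig2_final = s2(ny - 1) + pending;
}

// attenuation factors in the rotated frame (detector on the +y side):
// att(x,y,z) = exp(-dy * (0.5 * mu(x,y,z) + sum_{y'>y} mu(x,y',z)))
static cube attenuation_cube(const cube& mu_rot, double dy) {
  int nx = mu_rot.n_rows, ny = mu_rot.n_cols, nz = mu_rot.n_slices;
  cube att(nx, ny, nz);
  mat run(nx, nz, fill::zeros);
  for (int y = ny - 1; y >= 0; --y) {
    for (int k = 0; k < nz; ++k) {
      for (int i = 0; i < nx; ++i) {
        att(i, y, k) = std::exp(-(0.5 * mu_rot(i, y, k) * dy + run(i, k)));
        run(i, k) += mu_rot(i, y, k) * dy;
      }
    }
  }
  // run accumulated mu*dy; note the 0.5-voxel self-attenuation convention
  return att;
}

// project the rotated volume to the detector plane, multiplying the
// attenuation factors on the fly, with the depth-dependent psf (use_psf) or
// as a plain ray sum
static mat project_planes(const cube& rot, const cube& att, bool use_psf,
                          const vec& sig2_before, double sig2_final,
                          double du, double dv) {
  int nx = rot.n_rows, ny = rot.n_cols, nz = rot.n_slices;
  mat acc(nx, nz, fill::zeros);
  for (int y = 0; y < ny; ++y) {
    if (use_psf && sig2_before(y) > 0) {
      double s = std::sqrt(sig2_before(y));
      blur2d(acc, s / du, s / dv);
    }
    for (int k = 0; k < nz; ++k) {
      const double* r = rot.slice_memptr(k) + (size_t)nx * y;
      const double* a = att.slice_memptr(k) + (size_t)nx * y;
      double* o = acc.colptr(k);
      for (int i = 0; i < nx; ++i) o[i] += r[i] * a[i];
    }
  }
  if (use_psf && sig2_final > 0) {
    double s = std::sqrt(sig2_final);
    blur2d(acc, s / du, s / dv);
  }
  return acc;
}

// exact adjoint of project_planes: spread q back over depth planes (already
// attenuation-weighted), applying the recorded blur schedule in reverse
static void backspread_planes(const mat& q, const cube& att, bool use_psf,
                              const vec& sig2_before, double sig2_final,
                              double du, double dv, cube& w) {
  int nx = q.n_rows, nz = q.n_cols;
  int ny = att.n_cols;
  mat b = q;
  if (use_psf && sig2_final > 0) {
    double s = std::sqrt(sig2_final);
    blur2d(b, s / du, s / dv);
  }
  for (int y = ny - 1; y >= 0; --y) {
    for (int k = 0; k < nz; ++k) {
      const double* a = att.slice_memptr(k) + (size_t)nx * y;
      const double* bb = b.colptr(k);
      double* o = w.slice_memptr(k) + (size_t)nx * y;
      for (int i = 0; i < nx; ++i) o[i] = bb[i] * a[i];
    }
    if (use_psf && sig2_before(y) > 0 && y > 0) {
      double s = std::sqrt(sig2_before(y));
      blur2d(b, s / du, s / dv);
    }
  }
}

// ------------------------------------------------------------- entry points

// per-view attenuation cubes in the rotated detector frame
// [[Rcpp::export]]
Rcpp::List cpp_precompute_att(const arma::cube& mu, const arma::vec& spacing,
                              const arma::vec& angles_rad) {
  int nv = angles_rad.n_elem;
  Rcpp::List out(nv);
  cube mu_rot(mu.n_rows, mu.n_cols, mu.n_slices);
  for (int v = 0; v < nv; ++v) {
    RotMap rm = make_rotmap(mu.n_rows, mu.n_cols, angles_rad(v));
    rotate_cube(mu, rm, mu_rot);
    out[v] = attenuation_cube(mu_rot, spacing(1));
  }
  return out;
}

// forward projection of x (counts or concentration) through the attenuated,
// optionally psf-modelled system; returns (nu, nv, nviews)
// [[Rcpp::export]]
arma::cube cpp_forward(const arma::cube& x, Rcpp::List att_list,
                       const arma::vec& angles_rad, const arma::vec& spacing,
                       double det_radius, double fwhm_int, double psf_offset,
                       double psf_slope, bool use_psf, double scale) {
  int nx = x.n_rows, ny = x.n_cols, nz = x.n_slices;
  int nv = angles_rad.n_elem;
  vec s2b; double s2f;
  blur_schedule(ny, spacing(1), det_radius, fwhm_int, psf_offset, psf_slope,
                std::min(spacing(0), spacing(2)), s2b, s2f);
  cube p(nx, nz, nv, fill::zeros);
  cube rot(nx, ny, nz);
  for (int v = 0; v < nv; ++v) {
    RotMap rm = make_rotmap(nx, ny, angles_rad(v));
    rotate_cube(x, rm, rot);
    Rcpp::NumericVector av = att_list[v];
    const cube att(av.begin(), nx, ny, nz, false, true);
    p.slice(v) = scale * project_planes(rot, att, use_psf, s2b, s2f,
                                        spacing(0), spacing(2));
  }
  return p;
}

// adjoint of cpp_forward
// [[Rcpp::export]]
arma::cube cpp_backward(const arma::cube& q, Rcpp::List att_list,
                        const arma::vec& angles_rad, const arma::vec& spacing,
                        int ny, double det_radius, double fwhm_int,
                        double psf_offset, double psf_slope, bool use_psf,
                        double scale) {
  int nx = q.n_rows, nz = q.n_cols;
  int nv = angles_rad.n_elem;
  vec s2b; double s2f;
  blur_schedule(ny, spacing(1), det_radius, fwhm_int, psf_offset, psf_slope,
                std::min(spacing(0), spacing(2)), s2b, s2f);
  cube out(nx, ny, nz, fill::zeros);
  cube w(nx, ny, nz);
  for (int v = 0; v < nv; ++v) {
    mat qs = scale * q.slice(v);
    Rcpp::NumericVector av = att_list[v];
    const cube att(av.begin(), nx, ny, nz, false, true);
    backspread_planes(qs, att, use_psf, s2b, s2f, spacing(0), spacing(2), w);
    RotMap rm = make_rotmap(nx, ny, angles_rad(v));
    rotate_cube_adj(w, rm, out);
  }
  return out;
}

// full acquisition physics: photopeak = (1 - pen) * PSF(geom)
//   + pen * Gauss(pen_fwhm)(geom0) + width_ratio * alpha * Gauss(sc_fwhm)(geom0)
// scatter window = alpha * Gauss(sc_fwhm)(geom0), where geom0 is the plain
// attenuated ray sum and PSF the depth-dependent response; scale converts
// concentration-sums to expected counts per view
// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::cube& act, const arma::cube& mu,
                        const arma::vec& spacing, const arma::vec& angles_rad,
                        double det_radius, double fwhm_int, double psf_offset,
                        double psf_slope, double pen_fraction,
                        double pen_fwhm,
                        double scatter_alpha, double scatter_fwhm,
                        double width_ratio, double scale) {
  int nx = act.n_rows, ny = act.n_cols, nz = act.n_slices;
  int nv = angles_rad.n_elem;
  vec s2b; double s2f;
  blur_schedule(ny, spacing(1), det_radius, fwhm_int, psf_offset, psf_slope,
                std::min(spacing(0), spacing(2)), s2b, s2f);
  double ss = scatter_fwhm * FWHM_TO_SIGMA;
  double sp = pen_fwhm * FWHM_TO_SIGMA;
  cube peak(nx, nz, nv, fill::zeros), scat(nx, nz, nv, fill::zeros);
  cube rot(nx, ny, nz), mu_rot(nx, ny, nz);
  for (int v = 0; v < nv; ++v) {
    RotMap rm = make_rotmap(nx, ny, angles_rad(v));
    rotate_cube(act, rm, rot);
    rotate_cube(mu, rm, mu_rot);
    cube att = attenuation_cube(mu_rot, spacing(1));
    mat p0 = project_planes(rot, att, false, s2b, s2f, spacing(0), spacing(2));
    mat ppsf = project_planes(rot, att, true, s2b, s2f, spacing(0), spacing(2));
    mat ppen = p0, psc = p0;
    if (pen_fraction > 0) blur2d(ppen, sp / spacing(0), sp / spacing(2));
    if (scatter_alpha > 0) blur2d(psc, ss / spacing(0), ss / spacing(2));
    peak.slice(v) = scale * ((1.0 - pen_fraction) * ppsf +
                             pen_fraction * ppen +
                             width_ratio * scatter_alpha * psc);
    scat.slice(v) = scale * scatter_alpha * psc;
  }
  return Rcpp::List::create(Rcpp::Named("photopeak") = peak,
                            Rcpp::Named("scatter") = scat);
}

// --------------------------------------------------- relative difference prior

// U(x) = sum over unordered 26-neighbour pairs of
//   w_jk (x_j - x_k)^2 / (x_j + x_k + gamma |x_j - x_k| + eps),
// w_jk = 1 / (centre distance in voxel units); returns value and gradient
// [[Rcpp::export]]
Rcpp::List cpp_rdp(const arma::cube& x, double gamma, double eps,
                   bool want_grad) {
  int nx = x.n_rows, ny = x.n_cols, nz = x.n_slices;
  cube grad;
  if (want_grad) grad.zeros(nx, ny, nz);
  // half-space of the 26-neighbourhood: each unordered pair visited once
  std::vector<std::array<int, 3>> offs;
  std::vector<double> wts;
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (c > 0 || (c == 0 && b > 0) || (c == 0 && b == 0 && a > 0)) {
          offs.push_back({a, b, c});
          wts.push_back(1.0 / std::sqrt((double)(a * a + b * b + c * c)));
        }
      }
  double val = 0.0;
  for (size_t o = 0; o < offs.size(); ++o) {
    int a = offs[o][0], b = offs[o][1], c = offs[o][2];
    double w = wts[o];
    for (int k = std::max(0, -c); k < nz - std::max(0, c); ++k)
      for (int j = std::max(0, -b); j < ny - std::max(0, b); ++j)
        for (int i = std::max(0, -a); i < nx - std::max(0, a); ++i) {
          double xj = x(i, j, k), xk = x(i + a, j + b, k + c);
          double d = xj - xk;
          if (d == 0.0) continue;
          double ad = std::fabs(d);
          double D = xj + xk + gamma * ad + eps;
          val += w * d * d / D;
          if (want_grad) {
            double sg = (d > 0) ? 1.0 : -1.0;
            double gj = w * (2.0 * d * D - d * d * (1.0 + gamma * sg)) / (D * D);
            double gk = w * (-2.0 * d * D - d * d * (1.0 - gamma * sg)) / (D * D);
            grad(i, j, k) += gj;
            grad(i + a, j + b, k + c) += gk;
          }
        }
  }
  if (want_grad)
    return Rcpp::List::create(Rcpp::Named("value") = val,
                              Rcpp::Named("gradient") = grad);
  return Rcpp::List::create(Rcpp::Named("value") = val);
}

// ----------------------------------------------------------- image operators

// separable 3D Gaussian blur, sigma per axis in voxel units, zero padding
// [[Rcpp::export]]
arma::cube cpp_gauss_blur3(const arma::cube& v, const arma::vec& sigma_pix) {
  cube out = v;
  int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  if (sigma_pix(0) > 1e-8) {
    vec k = gauss_kernel(sigma_pix(0));
    for (int s = 0; s < nz; ++s) conv_cols(out.slice(s), k);
  }
  if (sigma_pix(1) > 1e-8) {
    vec k = gauss_kernel(sigma_pix(1));
    for (int s = 0; s < nz; ++s) {
      inplace_trans(out.slice(s));
      conv_cols(out.slice(s), k);
      inplace_trans(out.slice(s));
    }
  }
  if (sigma_pix(2) > 1e-8) {
    vec k = gauss_kernel(sigma_pix(2));
    int r = ((int)k.n_elem - 1) / 2;
    cube tmp(nx, ny, nz, fill::zeros);
    for (int s = 0; s < nz; ++s) {
      int lo = std::max(0, s - r), hi = std::min(nz - 1, s + r);
      for (int t = lo; t <= hi; ++t) tmp.slice(s) += out.slice(t) * k(s - t + r);
    }
    out = tmp;
  }
  return out;
}

// direct 3D convolution with an arbitrary (small, odd-sized) kernel
// [[Rcpp::export]]
arma::cube cpp_conv3(const arma::cube& v, const arma::cube& kern) {
  int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  int ra = (kern.n_rows - 1) / 2, rb = (kern.n_cols - 1) / 2,
      rc = (kern.n_slices - 1) / 2;
  cube out(nx, ny, nz, fill::zeros);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int c = -rc; c <= rc; ++c) {
          int kk = k + c;
          if (kk < 0 || kk >= nz) continue;
          for (int b = -rb; b <= rb; ++b) {
            int jj = j + b;
            if (jj < 0 || jj >= ny) continue;
            for (int a = -ra; a <= ra; ++a) {
              int ii = i + a;
              if (ii < 0 || ii >= nx) continue;
              s += v(ii, jj, kk) * kern(a + ra, b + rb, c + rc);
            }
          }
        }
        out(i, j, k) = s;
      }
  return out;
}

// trilinear resampling of vol (world-aligned grids, mm units); values outside
// the source grid are zero
// [[Rcpp::export]]
arma::cube cpp_resample_trilinear(const arma::cube& vol,
                                  const arma::vec& src_spacing,
                                  const arma::vec& src_origin,
                                  const arma::ivec& dst_dim,
                                  const arma::vec& dst_spacing,
                                  const arma::vec& dst_origin) {
  int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  cube out(dst_dim(0), dst_dim(1), dst_dim(2), fill::zeros);
  for (int k = 0; k < dst_dim(2); ++k)
    for (int j = 0; j < dst_dim(1); ++j)
      for (int i = 0; i < dst_dim(0); ++i) {
        double xs = (dst_origin(0) + i * dst_spacing(0) - src_origin(0)) / src_spacing(0);
        double ys = (dst_origin(1) + j * dst_spacing(1) - src_origin(1)) / src_spacing(1);
        double zs = (dst_origin(2) + k * dst_spacing(2) - src_origin(2)) / src_spacing(2);
        int i0 = (int)std::floor(xs), j0 = (int)std::floor(ys),
            k0 = (int)std::floor(zs);
        if (i0 < -1 || i0 > nx - 1 || j0 < -1 || j0 > ny - 1 ||
            k0 < -1 || k0 > nz - 1)
          continue;
        double fx = xs - i0, fy = ys - j0, fz = zs - k0;
        double s = 0.0;
        for (int c = 0; c <= 1; ++c) {
          int kk = k0 + c;
          if (kk < 0 || kk >= nz) continue;
          double wz = c ? fz : 1 - fz;
          for (int b = 0; b <= 1; ++b) {
            int jj = j0 + b;
            if (jj < 0 || jj >= ny) continue;
            double wy = b ? fy : 1 - fy;
            for (int a = 0; a <= 1; ++a) {
              int ii = i0 + a;
              if (ii < 0 || ii >= nx) continue;
              double wx = a ? fx : 1 - fx;
              s += wx * wy * wz * vol(ii, jj, kk);
            }
          }
        }
        out(i, j, k) = s;
      }
  return out;
}

// 26-connected component of a logical mask containing seed (0-based indices)
// [[Rcpp::export]]
arma::ucube cpp_connected_component(const arma::ucube& mask, int si, int sj,
                                    int sk) {
  int nx = mask.n_rows, ny = mask.n_cols, nz = mask.n_slices;
  ucube out(nx, ny, nz, fill::zeros);
  if (si < 0 || si >= nx || sj < 0 || sj >= ny || sk < 0 || sk >= nz)
    Rcpp::stop("seed outside the volume");
  if (!mask(si, sj, sk)) return out;
  std::vector<std::array<int, 3>> stack;
  stack.push_back({si, sj, sk});
  out(si, sj, sk) = 1;
  while (!stack.empty()) {
    auto p = stack.back();
    stack.pop_back();
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          if (!a && !b && !c) continue;
          int i = p[0] + a, j = p[1] + b, k = p[2] + c;
          if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
            continue;
          if (mask(i, j, k) && !out(i, j, k)) {
            out(i, j, k) = 1;
            stack.push_back({i, j, k});
          }
        }
  }
  return out;
}
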