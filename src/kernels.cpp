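#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Column-major linear index into a 3D array of extents nx,ny,nz.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Trilinear sample of src at continuous voxel coordinate (x,y,z), 0-based.
// Out-of-field contributions are 0 (the package-wide fill convention).
static inline double sample_tri(const double* src, int nx, int ny, int nz,
                                double x, double y, double z) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= nz) continue;
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy;
      if (yy < 0 || yy >= ny) continue;
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= nx) continue;
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        out += wx * wy * wz * src[lin(xx, yy, zz, nx, ny)];
      }
    }
  }
  return out;
}

static inline double sample_nn(const double* src, int nx, int ny, int nz,
                               double x, double y, double z) {
  int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
  if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz) return 0.0;
  return src[lin(xi, yi, zi, nx, ny)];
}

// Resample src (dims sdim) onto an output grid (dims odim) through the
// 4x4 map M taking output voxel indices to source voxel coordinates.
// interp: 0 = nearest, 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector sdim,
                           NumericMatrix M, IntegerVector odim, int interp) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* s = src.begin();
  double* o = out.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = m00 * i + bx, y = m10 * i + by, z = m20 * i + bz;
        o[idx] = interp ? sample_tri(s, nx, ny, nz, x, y, z)
                        : sample_nn(s, nx, ny, nz, x, y, z);
      }
    }
  }
  return out;
}

// Mean squared difference between fixed and the moving image pulled through
// M (fixed voxel -> moving voxel), evaluated on a stride-`step` subgrid of
// the fixed image.  Out-of-field moving samples count as 0.
// [[Rcpp::export]]
double cpp_cost_ssd(NumericVector mov, IntegerVector mdim,
                    NumericVector fix, IntegerVector fdim,
                    NumericMatrix M, int step, LogicalVector fmask) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const double* mv = mov.begin();
  const double* fv = fix.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  bool useMask = fmask.size() > 0;
  double acc = 0.0;
  R_xlen_t n = 0;
  for (int k = 0; k < fz; k += step) {
    for (int j = 0; j < fy; j += step) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < fx; i += step) {
        if (useMask && !fmask[lin(i, j, k, fx, fy)]) continue;
        double x = m00 * i + bx, y = m10 * i + by, z = m20 * i + bz;
        double d = fv[lin(i, j, k, fx, fy)] - sample_tri(mv, nx, ny, nz, x, y, z);
        acc += d * d;
        ++n;
      }
    }
  }
  return n > 0 ? acc / (double)n : R_PosInf;
}

// Per-sample residuals fixed - moving(M * voxel) on a stride-`step` subgrid
// of the fixed image (for Gauss-Newton style SSD minimization).
// [[Rcpp::export]]
NumericVector cpp_resid_ssd(NumericVector mov, IntegerVector mdim,
                            NumericVector fix, IntegerVector fdim,
                            NumericMatrix M, int step, LogicalVector fmask) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const double* mv = mov.begin();
  const double* fv = fix.begin();
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  bool useMask = fmask.size() > 0;
  std::vector<double> vals;
  vals.reserve(((R_xlen_t)fx * fy * fz) / (step * step * step) + 1);
  for (int k = 0; k < fz; k += step) {
    for (int j = 0; j < fy; j += step) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < fx; i += step) {
        if (useMask && !fmask[lin(i, j, k, fx, fy)]) continue;
        double x = m00 * i + bx, y = m10 * i + by, z = m20 * i + bz;
        vals.push_back(fv[lin(i, j, k, fx, fy)] -
                       sample_tri(mv, nx, ny, nz, x, y, z));
      }
    }
  }
  return NumericVector(vals.begin(), vals.end());
}

// Joint histogram of fixed vs moving-pulled-through-M over their overlap,
// with bilinear fractional bin assignment on both axes (smooth NMI surface).
// Samples whose mapped moving coordinate is out of field are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector mov, IntegerVector mdim,
                             NumericVector fix, IntegerVector fdim,
                             NumericMatrix M, int step, int bins,
                             double fmin, double fmax,
                             double mmin, double mmax,
                             LogicalVector fmask) {
  int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  int fx = fdim[0], fy = fdim[1], fz = fdim[2];
  const double* mv = mov.begin();
  const double* fv = fix.begin();
  NumericMatrix H(bins, bins);
  double fscale = (bins - 1) / std::max(fmax - fmin, 1e-12);
  double mscale = (bins - 1) / std::max(mmax - mmin, 1e-12);
  double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  for (int k = 0; k < fz; k += step) {
    for (int j = 0; j < fy; j += step) {
      double bx = m01 * j + m02 * k + m03;
      double by = m11 * j + m12 * k + m13;
      double bz = m21 * j + m22 * k + m23;
      for (int i = 0; i < fx; i += step) {
        if (fmask.size() > 0 && !fmask[lin(i, j, k, fx, fy)]) continue;
        double x = m00 * i + bx, y = m10 * i + by, z = m20 * i + bz;
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1)
          continue;
        double mval = sample_tri(mv, nx, ny, nz, x, y, z);
        double fval = fv[lin(i, j, k, fx, fy)];
        double fb = (fval - fmin) * fscale, mb = (mval - mmin) * mscale;
        if (fb < 0) fb = 0; if (fb > bins - 1) fb = bins - 1;
        if (mb < 0) mb = 0; if (mb > bins - 1) mb = bins - 1;
        int f0 = (int)fb, m0 = (int)mb;
        double ff = fb - f0, mf = mb - m0;
        int f1 = f0 + (f0 < bins - 1), m1 = m0 + (m0 < bins - 1);
        H(f0, m0) += (1 - ff) * (1 - mf);
        H(f1, m0) += ff * (1 - mf);
        H(f0, m1) += (1 - ff) * mf;
        H(f1, m1) += ff * mf;
      }
    }
  }
  return H;
}

// Separable Gaussian smoothing, sigma in voxels per axis, kernels truncated
// at 3 sigma and renormalized.  boundary: 0 = mirror reflection
// (intensity conserving), 1 = zero padding.  Implemented with contiguous
// x-row inner loops on every axis for cache efficiency.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector x, IntegerVector dim,
                               NumericVector sigma_vox, int boundary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> buf(x.begin(), x.end());
  std::vector<double> tmp(ntot);
  auto make_kernel = [](double s, std::vector<double>& kern) {
    int r = std::max(1, (int)std::ceil(3.0 * s));
    kern.assign(2 * r + 1, 0.0);
    double ksum = 0.0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (s * s));
      ksum += kern[t + r];
    }
    for (double& v : kern) v /= ksum;
    return r;
  };
  auto reflect = [](int q, int n) {
    while (q < 0 || q >= n) {
      if (n == 1) return 0;
      if (q < 0) q = -q;
      if (q >= n) q = 2 * n - 2 - q;
    }
    return q;
  };
  std::vector<double> kern;

  // x axis: direct per-line convolution (lines are contiguous)
  if (sigma_vox[0] > 0) {
    int r = make_kernel(sigma_vox[0], kern);
    for (R_xlen_t line = 0; line < (R_xlen_t)ny * nz; ++line) {
      double* src = buf.data() + line * nx;
      double* dst = tmp.data() + line * nx;
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        if (i - r >= 0 && i + r < nx) {
          for (int t = -r; t <= r; ++t) acc += kern[t + r] * src[i + t];
        } else {
          for (int t = -r; t <= r; ++t) {
            int q = i + t;
            if (q < 0 || q >= nx) {
              if (boundary == 1) continue;
              q = reflect(q, nx);
            }
            acc += kern[t + r] * src[q];
          }
        }
        dst[i] = acc;
      }
    }
    std::swap(buf, tmp);
  }

  // y and z axes: accumulate whole x-rows (contiguous) per kernel tap
  for (int ax = 1; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = make_kernel(s, kern);
    int n = (ax == 1) ? ny : nz;
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        int p = (ax == 1) ? j : k;
        double* dst = tmp.data() + ((R_xlen_t)k * ny + j) * nx;
        for (int t = -r; t <= r; ++t) {
          int q = p + t;
          if (q < 0 || q >= n) {
            if (boundary == 1) continue;
            q = reflect(q, n);
          }
          const double* src = (ax == 1)
            ? buf.data() + ((R_xlen_t)k * ny + q) * nx
            : buf.data() + ((R_xlen_t)q * ny + j) * nx;
          double w = kern[t + r];
          for (int i = 0; i < nx; ++i) dst[i] += w * src[i];
        }
      }
    }
    std::swap(buf, tmp);
  }
  return NumericVector(buf.begin(), buf.end());
}

// Connected-component labeling of a binary field.  connectivity in {6,18,26}.
// Returns integer labels, 0 = background, components numbered from 1 in
// first-voxel raster order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot);
  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs_i.push_back(di); offs_j.push_back(dj); offs_k.push_back(dk);
      }
  int nofs = (int)offs_i.size();
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t v = lin(i, j, k, nx, ny);
        if (!mask[v] || lab[v]) continue;
        lab[v] = ++cur;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          R_xlen_t p = stack.back(); stack.pop_back();
          int pi = (int)(p % nx), pj = (int)((p / nx) % ny), pk = (int)(p / ((R_xlen_t)nx * ny));
          for (int t = 0; t < nofs; ++t) {
            int qi = pi + offs_i[t], qj = pj + offs_j[t], qk = pk + offs_k[t];
            if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 || qk >= nz)
              continue;
            R_xlen_t q = lin(qi, qj, qk, nx, ny);
            if (mask[q] && !lab[q]) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
        }
      }
  lab.attr("n_components") = cur;
  return lab;
}
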