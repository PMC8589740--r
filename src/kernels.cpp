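// Low-level voxel kernels: 3D convolution (forward/backward) for the
// segmentation network, resampling under affine + displacement maps,
// separable Gaussian and nonlocal-means filters, binary morphology,
// connected components, voxelwise percentiles and nearest-site labelling.
// All arrays are column-major with dims [X, Y, Z] or [X, Y, Z, C].
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// output index range [lo, hi) such that i*stride - pad + koff lies in
// [0, n) for every i in the range
static inline void conv_bounds(int n_out, int n_in, int stride, int pad,
                               int koff, int &lo, int &hi) {
  const int shift = koff - pad;
  lo = 0;
  while (lo < n_out && lo * stride + shift < 0) ++lo;
  hi = n_out;
  while (hi > lo && (hi - 1) * stride + shift >= n_in) --hi;
}

// [[Rcpp::export(name = ".cq_conv3d_fwd")]]
NumericVector cq_conv3d_fwd(NumericVector x, NumericVector W,
                            NumericVector b, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int k = wd[0], Co = wd[4];
  if (wd[3] != Ci) stop("channel mismatch between input and weights");
  const int Xo = out_extent(X, k, stride, pad);
  const int Yo = out_extent(Y, k, stride, pad);
  const int Zo = out_extent(Z, k, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(Xo) * Yo * Zo * Co);
  const double *px = x.begin(), *pw = W.begin(), *pb = b.begin();
  double *py = y.begin();
  const R_xlen_t xsY = X, xsZ = static_cast<R_xlen_t>(X) * Y,
                 xsC = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t ysY = Xo, ysZ = static_cast<R_xlen_t>(Xo) * Yo,
                 ysC = static_cast<R_xlen_t>(Xo) * Yo * Zo;
  const R_xlen_t wsc = static_cast<R_xlen_t>(k) * k * k, wso = wsc * Ci;
  for (int co = 0; co < Co; ++co) {
    double *yc = py + co * ysC;
    const double bc = pb[co];
    for (R_xlen_t i = 0; i < ysC; ++i) yc[i] = bc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + ci * xsC;
      const double *wc = pw + co * wso + ci * wsc;
      for (int kz = 0; kz < k; ++kz) {
        int zlo, zhi;
        conv_bounds(Zo, Z, stride, pad, kz, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          int ylo, yhi;
          conv_bounds(Yo, Y, stride, pad, ky, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            const double w = wc[kx + k * (ky + k * kz)];
            if (w == 0.0) continue;
            int xlo, xhi;
            conv_bounds(Xo, X, stride, pad, kx, xlo, xhi);
            const int xshift = kx - pad, yshift = ky - pad,
                      zshift = kz - pad;
            for (int zo = zlo; zo < zhi; ++zo) {
              const double *xz = xc + (zo * stride + zshift) * xsZ;
              double *yz = yc + zo * ysZ;
              for (int yo = ylo; yo < yhi; ++yo) {
                const double *xrow = xz + (yo * stride + yshift) * xsY +
                                     xshift;
                double *yrow = yz + yo * ysY;
                if (stride == 1) {
                  for (int xo = xlo; xo < xhi; ++xo)
                    yrow[xo] += w * xrow[xo];
                } else {
                  for (int xo = xlo; xo < xhi; ++xo)
                    yrow[xo] += w * xrow[xo * stride];
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, Co);
  return y;
}

// Gradient w.r.t. the input of cq_conv3d_fwd; doubles as the forward pass of
// a transposed (up-sampling) convolution.
// [[Rcpp::export(name = ".cq_conv3d_bwd_input")]]
NumericVector cq_conv3d_bwd_input(NumericVector gy, NumericVector W,
                                  IntegerVector in_dim, int stride, int pad) {
  IntegerVector gd = gy.attr("dim");
  IntegerVector wd = W.attr("dim");
  const int Xo = gd[0], Yo = gd[1], Zo = gd[2], Co = gd[3];
  const int k = wd[0], Ci = wd[3];
  if (wd[4] != Co) stop("channel mismatch between gradient and weights");
  const int X = in_dim[0], Y = in_dim[1], Z = in_dim[2];
  NumericVector gx(static_cast<R_xlen_t>(X) * Y * Z * Ci);
  const double *pg = gy.begin(), *pw = W.begin();
  double *px = gx.begin();
  const R_xlen_t xsY = X, xsZ = static_cast<R_xlen_t>(X) * Y,
                 xsC = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t ysY = Xo, ysZ = static_cast<R_xlen_t>(Xo) * Yo,
                 ysC = static_cast<R_xlen_t>(Xo) * Yo * Zo;
  const R_xlen_t wsc = static_cast<R_xlen_t>(k) * k * k, wso = wsc * Ci;
  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + co * ysC;
    for (int ci = 0; ci < Ci; ++ci) {
      double *xc = px + ci * xsC;
      const double *wc = pw + co * wso + ci * wsc;
      for (int kz = 0; kz < k; ++kz) {
        int zlo, zhi;
        conv_bounds(Zo, Z, stride, pad, kz, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          int ylo, yhi;
          conv_bounds(Yo, Y, stride, pad, ky, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            const double w = wc[kx + k * (ky + k * kz)];
            if (w == 0.0) continue;
            int xlo, xhi;
            conv_bounds(Xo, X, stride, pad, kx, xlo, xhi);
            const int xshift = kx - pad, yshift = ky - pad,
                      zshift = kz - pad;
            for (int zo = zlo; zo < zhi; ++zo) {
              double *xz = xc + (zo * stride + zshift) * xsZ;
              const double *gz = gc + zo * ysZ;
              for (int yo = ylo; yo < yhi; ++yo) {
                double *xrow = xz + (yo * stride + yshift) * xsY + xshift;
                const double *grow = gz + yo * ysY;
                if (stride == 1) {
                  for (int xo = xlo; xo < xhi; ++xo)
                    xrow[xo] += w * grow[xo];
                } else {
                  for (int xo = xlo; xo < xhi; ++xo)
                    xrow[xo * stride] += w * grow[xo];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  return gx;
}

// [[Rcpp::export(name = ".cq_conv3d_bwd_weights")]]
List cq_conv3d_bwd_weights(NumericVector x, NumericVector gy, int k,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int Xo = gd[0], Yo = gd[1], Zo = gd[2], Co = gd[3];
  NumericVector gW(static_cast<R_xlen_t>(k) * k * k * Ci * Co);
  NumericVector gb(Co);
  const double *px = x.begin(), *pg = gy.begin();
  double *pW = gW.begin(), *pbg = gb.begin();
  const R_xlen_t xsY = X, xsZ = static_cast<R_xlen_t>(X) * Y,
                 xsC = static_cast<R_xlen_t>(X) * Y * Z;
  const R_xlen_t ysY = Xo, ysZ = static_cast<R_xlen_t>(Xo) * Yo,
                 ysC = static_cast<R_xlen_t>(Xo) * Yo * Zo;
  const R_xlen_t wsc = static_cast<R_xlen_t>(k) * k * k, wso = wsc * Ci;
  for (int co = 0; co < Co; ++co) {
    const double *gc = pg + co * ysC;
    double bacc = 0;
    for (R_xlen_t i = 0; i < ysC; ++i) bacc += gc[i];
    pbg[co] = bacc;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + ci * xsC;
      double *wc = pW + co * wso + ci * wsc;
      for (int kz = 0; kz < k; ++kz) {
        int zlo, zhi;
        conv_bounds(Zo, Z, stride, pad, kz, zlo, zhi);
        for (int ky = 0; ky < k; ++ky) {
          int ylo, yhi;
          conv_bounds(Yo, Y, stride, pad, ky, ylo, yhi);
          for (int kx = 0; kx < k; ++kx) {
            int xlo, xhi;
            conv_bounds(Xo, X, stride, pad, kx, xlo, xhi);
            const int xshift = kx - pad, yshift = ky - pad,
                      zshift = kz - pad;
            double acc = 0;
            for (int zo = zlo; zo < zhi; ++zo) {
              const double *xz = xc + (zo * stride + zshift) * xsZ;
              const double *gz = gc + zo * ysZ;
              for (int yo = ylo; yo < yhi; ++yo) {
                const double *xrow = xz + (yo * stride + yshift) * xsY +
                                     xshift;
                const double *grow = gz + yo * ysY;
                if (stride == 1) {
                  // four independent accumulators break the serial
                  // dependency so the reduction can pipeline/vectorize
                  double a0 = 0, a1 = 0, a2 = 0, a3 = 0;
                  int xo = xlo;
                  for (; xo + 3 < xhi; xo += 4) {
                    a0 += grow[xo] * xrow[xo];
                    a1 += grow[xo + 1] * xrow[xo + 1];
                    a2 += grow[xo + 2] * xrow[xo + 2];
                    a3 += grow[xo + 3] * xrow[xo + 3];
                  }
                  for (; xo < xhi; ++xo) a0 += grow[xo] * xrow[xo];
                  acc += (a0 + a1) + (a2 + a3);
                } else {
                  for (int xo = xlo; xo < xhi; ++xo)
                    acc += grow[xo] * xrow[xo * stride];
                }
              }
            }
            wc[kx + k * (ky + k * kz)] += acc;
          }
        }
      }
    }
  }
  gW.attr("dim") = IntegerVector::create(k, k, k, Ci, Co);
  return List::create(_["gW"] = gW, _["gb"] = gb);
}

static inline double sample_linear(const double *v, int X, int Y, int Z,
                                   double fx, double fy, double fz,
                                   double fill) {
  if (fx < 0 || fy < 0 || fz < 0 || fx > X - 1 || fy > Y - 1 || fz > Z - 1)
    return fill;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
      z0 = (int)std::floor(fz);
  if (x0 == X - 1) x0--;
  if (y0 == Y - 1) y0--;
  if (z0 == Z - 1) z0--;
  if (X == 1) x0 = 0;
  if (Y == 1) y0 = 0;
  if (Z == 1) z0 = 0;
  const double dx = fx - x0, dy = fy - y0, dz = fz - z0;
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  const int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1),
            z1 = std::min(z0 + 1, Z - 1);
  double c00 = v[x0 + y0 * sY + z0 * sZ] * (1 - dx) +
               v[x1 + y0 * sY + z0 * sZ] * dx;
  double c10 = v[x0 + y1 * sY + z0 * sZ] * (1 - dx) +
               v[x1 + y1 * sY + z0 * sZ] * dx;
  double c01 = v[x0 + y0 * sY + z1 * sZ] * (1 - dx) +
               v[x1 + y0 * sY + z1 * sZ] * dx;
  double c11 = v[x0 + y1 * sY + z1 * sZ] * (1 - dx) +
               v[x1 + y1 * sY + z1 * sZ] * dx;
  return (c00 * (1 - dy) + c10 * dy) * (1 - dz) +
         (c01 * (1 - dy) + c11 * dy) * dz;
}

// Catmull-Rom cubic convolution (a = -0.5); sharper than trilinear for
// structures spanning one or two voxels. Border handled by index clamp.
static inline double cubic_w(double t) {
  t = std::fabs(t);
  if (t <= 1) return 1.5 * t * t * t - 2.5 * t * t + 1;
  if (t < 2) return -0.5 * t * t * t + 2.5 * t * t - 4 * t + 2;
  return 0;
}

static inline double sample_cubic(const double *v, int X, int Y, int Z,
                                  double fx, double fy, double fz,
                                  double fill) {
  if (fx < 0 || fy < 0 || fz < 0 || fx > X - 1 || fy > Y - 1 || fz > Z - 1)
    return fill;
  const int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
            z0 = (int)std::floor(fz);
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  double acc = 0, wsum = 0;
  for (int dz = -1; dz <= 2; ++dz) {
    const int zi = std::min(std::max(z0 + dz, 0), Z - 1);
    const double wz = cubic_w(fz - (z0 + dz));
    if (wz == 0) continue;
    for (int dy = -1; dy <= 2; ++dy) {
      const int yi = std::min(std::max(y0 + dy, 0), Y - 1);
      const double wy = cubic_w(fy - (y0 + dy));
      if (wy == 0) continue;
      const double wyz = wy * wz;
      const R_xlen_t rowb = yi * sY + zi * sZ;
      for (int dx = -1; dx <= 2; ++dx) {
        const int xi = std::min(std::max(x0 + dx, 0), X - 1);
        const double w = cubic_w(fx - (x0 + dx)) * wyz;
        acc += w * v[xi + rowb];
        wsum += w;
      }
    }
  }
  return wsum != 0 ? acc / wsum : fill;
}

static inline double sample_nearest(const double *v, int X, int Y, int Z,
                                    double fx, double fy, double fz,
                                    double fill) {
  const int xi = (int)std::floor(fx + 0.5), yi = (int)std::floor(fy + 0.5),
            zi = (int)std::floor(fz + 0.5);
  if (xi < 0 || yi < 0 || zi < 0 || xi >= X || yi >= Y || zi >= Z) return fill;
  return v[xi + static_cast<R_xlen_t>(X) * yi +
           static_cast<R_xlen_t>(X) * Y * zi];
}

// Resample `vol` (grid: src_spacing/src_origin) onto the destination grid.
// For each destination voxel with world coordinate w the source world
// coordinate is p = A %*% w, optionally refined by a displacement field
// `disp` (mm, dims [Xd,Yd,Zd,3] on the disp grid): p' = p + disp(p).
// method: 0 nearest, 1 trilinear.
// [[Rcpp::export(name = ".cq_resample")]]
NumericVector cq_resample(NumericVector vol, NumericVector src_spacing,
                          NumericVector src_origin, IntegerVector dst_dim,
                          NumericVector dst_spacing, NumericVector dst_origin,
                          NumericMatrix A, NumericVector disp,
                          NumericVector disp_spacing,
                          NumericVector disp_origin, int method, double fill) {
  IntegerVector vd = vol.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int Xd = dst_dim[0], Yd = dst_dim[1], Zd = dst_dim[2];
  const bool have_disp = disp.size() > 0;
  int DX = 0, DY = 0, DZ = 0;
  const double *pd = nullptr;
  R_xlen_t dC = 0;
  if (have_disp) {
    IntegerVector dd = disp.attr("dim");
    DX = dd[0]; DY = dd[1]; DZ = dd[2];
    pd = disp.begin();
    dC = static_cast<R_xlen_t>(DX) * DY * DZ;
  }
  NumericVector out(static_cast<R_xlen_t>(Xd) * Yd * Zd);
  const double *pv = vol.begin();
  double *po = out.begin();
  R_xlen_t oi = 0;
  for (int z = 0; z < Zd; ++z) {
    const double wz = dst_origin[2] + z * dst_spacing[2];
    for (int y = 0; y < Yd; ++y) {
      const double wy = dst_origin[1] + y * dst_spacing[1];
      for (int x = 0; x < Xd; ++x, ++oi) {
        const double wx = dst_origin[0] + x * dst_spacing[0];
        double px = A(0, 0) * wx + A(0, 1) * wy + A(0, 2) * wz + A(0, 3);
        double py = A(1, 0) * wx + A(1, 1) * wy + A(1, 2) * wz + A(1, 3);
        double pz = A(2, 0) * wx + A(2, 1) * wy + A(2, 2) * wz + A(2, 3);
        if (have_disp) {
          const double gx = (px - disp_origin[0]) / disp_spacing[0];
          const double gy = (py - disp_origin[1]) / disp_spacing[1];
          const double gz = (pz - disp_origin[2]) / disp_spacing[2];
          px += sample_linear(pd, DX, DY, DZ, gx, gy, gz, 0.0);
          py += sample_linear(pd + dC, DX, DY, DZ, gx, gy, gz, 0.0);
          pz += sample_linear(pd + 2 * dC, DX, DY, DZ, gx, gy, gz, 0.0);
        }
        const double fx = (px - src_origin[0]) / src_spacing[0];
        const double fy = (py - src_origin[1]) / src_spacing[1];
        const double fz = (pz - src_origin[2]) / src_spacing[2];
        po[oi] = method == 0
                     ? sample_nearest(pv, X, Y, Z, fx, fy, fz, fill)
                     : (method == 2
                            ? sample_cubic(pv, X, Y, Z, fx, fy, fz, fill)
                            : sample_linear(pv, X, Y, Z, fx, fy, fz, fill));
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Xd, Yd, Zd);
  return out;
}

// Mean squared difference between `fix` and `vol` resampled (trilinear,
// fill 0) through the affine A (dst world -> src world). Fused so the
// registration objective avoids allocating a resampled volume per call.
// [[Rcpp::export(name = ".cq_ssd_affine")]]
double cq_ssd_affine(NumericVector vol, NumericVector src_spacing,
                     NumericVector src_origin, NumericVector fix,
                     IntegerVector dst_dim, NumericVector dst_spacing,
                     NumericVector dst_origin, NumericMatrix A) {
  IntegerVector vd = vol.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int Xd = dst_dim[0], Yd = dst_dim[1], Zd = dst_dim[2];
  const double *pv = vol.begin(), *pf = fix.begin();
  double acc = 0;
  R_xlen_t oi = 0;
  for (int z = 0; z < Zd; ++z) {
    const double wz = dst_origin[2] + z * dst_spacing[2];
    for (int y = 0; y < Yd; ++y) {
      const double wy = dst_origin[1] + y * dst_spacing[1];
      const double bx = A(0, 1) * wy + A(0, 2) * wz + A(0, 3);
      const double by = A(1, 1) * wy + A(1, 2) * wz + A(1, 3);
      const double bz = A(2, 1) * wy + A(2, 2) * wz + A(2, 3);
      for (int x = 0; x < Xd; ++x, ++oi) {
        const double wx = dst_origin[0] + x * dst_spacing[0];
        const double fx = (A(0, 0) * wx + bx - src_origin[0]) /
                          src_spacing[0];
        const double fy = (A(1, 0) * wx + by - src_origin[1]) /
                          src_spacing[1];
        const double fz = (A(2, 0) * wx + bz - src_origin[2]) /
                          src_spacing[2];
        const double m = sample_linear(pv, X, Y, Z, fx, fy, fz, 0.0);
        const double d = pf[oi] - m;
        acc += d * d;
      }
    }
  }
  return acc / (static_cast<double>(Xd) * Yd * Zd);
}

// SSD evaluated over an explicit list of fixed-image sample points
// (world coordinates, with their fixed values): used at the fine
// registration levels, where only the mask-support voxels are
// informative and evaluating the full grid wastes most of the time.
// [[Rcpp::export(name = ".cq_ssd_affine_pts")]]
double cq_ssd_affine_pts(NumericVector vol, NumericVector src_spacing,
                         NumericVector src_origin, NumericMatrix pts,
                         NumericVector fvals, NumericMatrix A) {
  IntegerVector vd = vol.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const double *pv = vol.begin();
  const int n = pts.nrow();
  double acc = 0;
  for (int i = 0; i < n; ++i) {
    const double wx = pts(i, 0), wy = pts(i, 1), wz = pts(i, 2);
    const double px = A(0, 0) * wx + A(0, 1) * wy + A(0, 2) * wz + A(0, 3);
    const double py = A(1, 0) * wx + A(1, 1) * wy + A(1, 2) * wz + A(1, 3);
    const double pz = A(2, 0) * wx + A(2, 1) * wy + A(2, 2) * wz + A(2, 3);
    const double m = sample_linear(pv, X, Y, Z,
                                   (px - src_origin[0]) / src_spacing[0],
                                   (py - src_origin[1]) / src_spacing[1],
                                   (pz - src_origin[2]) / src_spacing[2],
                                   0.0);
    const double dd = fvals[i] - m;
    acc += dd * dd;
  }
  return acc / n;
}

// Separable Gaussian blur, kernel truncated at 3 sigma and renormalized at
// the edges.
// [[Rcpp::export(name = ".cq_gauss3")]]
NumericVector cq_gauss3(NumericVector vol, NumericVector sigma_vox) {
  IntegerVector vd = vol.attr("dim");
  const int dims[3] = {vd[0], vd[1], vd[2]};
  NumericVector cur = clone(vol);
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma_vox[ax];
    if (s <= 0) continue;
    const int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    for (int i = -r; i <= r; ++i)
      kern[i + r] = std::exp(-0.5 * (i * i) / (s * s));
    NumericVector nxt(cur.size());
    const int X = dims[0], Y = dims[1], Z = dims[2];
    const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
    const R_xlen_t step = ax == 0 ? 1 : (ax == 1 ? sY : sZ);
    const int n = dims[ax];
    const double *pc = cur.begin();
    double *pn = nxt.begin();
    for (int z = 0; z < Z; ++z) {
      for (int y = 0; y < Y; ++y) {
        for (int x = 0; x < X; ++x) {
          const int pos = ax == 0 ? x : (ax == 1 ? y : z);
          const R_xlen_t base = x + y * sY + z * sZ;
          double acc = 0, wsum = 0;
          const int lo = std::max(-r, -pos), hi = std::min(r, n - 1 - pos);
          for (int i = lo; i <= hi; ++i) {
            const double w = kern[i + r];
            acc += w * pc[base + i * step];
            wsum += w;
          }
          pn[base] = acc / wsum;
        }
      }
    }
    cur = nxt;
  }
  cur.attr("dim") = vd;
  return cur;
}

// Nonlocal-means denoising. Per search offset d the squared-difference
// image (I(v) - I(clamp(v + d)))^2 is box-averaged over the patch by three
// separable passes, giving the patch distance for all voxels at once; the
// weight is exp(-patch_mean / h^2).
static void box_mean_axis(std::vector<double> &v, std::vector<double> &tmp,
                          int X, int Y, int Z, int r, int axis) {
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  const int n = axis == 0 ? X : (axis == 1 ? Y : Z);
  const R_xlen_t step = axis == 0 ? 1 : (axis == 1 ? sY : sZ);
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const int pos = axis == 0 ? x : (axis == 1 ? y : z);
        const R_xlen_t base = x + y * sY + z * sZ;
        const int lo = std::max(-r, -pos), hi = std::min(r, n - 1 - pos);
        double acc = 0;
        for (int i = lo; i <= hi; ++i) acc += v[base + i * step];
        tmp[base] = acc / (hi - lo + 1);
      }
  v.swap(tmp);
}

// [[Rcpp::export(name = ".cq_nlm")]]
NumericVector cq_nlm(NumericVector vol, int patch_r, int search_r, double h) {
  IntegerVector vd = vol.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const R_xlen_t V = vol.size();
  NumericVector out(V);
  const double *pv = vol.begin();
  double *po = out.begin();
  if (h <= 0) {
    std::copy(pv, pv + V, po);
    out.attr("dim") = vd;
    return out;
  }
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  const double h2 = h * h;
  std::vector<double> sq(V), tmp(V), wsum(V, 0.0), acc(V, 0.0);
  for (int dz = -search_r; dz <= search_r; ++dz) {
    for (int dy = -search_r; dy <= search_r; ++dy) {
      for (int dx = -search_r; dx <= search_r; ++dx) {
        R_xlen_t i;
        i = 0;
        for (int z = 0; z < Z; ++z) {
          const int z2 = std::min(std::max(z + dz, 0), Z - 1);
          for (int y = 0; y < Y; ++y) {
            const int y2 = std::min(std::max(y + dy, 0), Y - 1);
            const R_xlen_t rowb = y2 * sY + z2 * sZ;
            for (int x = 0; x < X; ++x, ++i) {
              const int x2 = std::min(std::max(x + dx, 0), X - 1);
              const double d = pv[i] - pv[x2 + rowb];
              sq[i] = d * d;
            }
          }
        }
        box_mean_axis(sq, tmp, X, Y, Z, patch_r, 0);
        box_mean_axis(sq, tmp, X, Y, Z, patch_r, 1);
        box_mean_axis(sq, tmp, X, Y, Z, patch_r, 2);
        i = 0;
        for (int z = 0; z < Z; ++z) {
          const int z2 = std::min(std::max(z + dz, 0), Z - 1);
          for (int y = 0; y < Y; ++y) {
            const int y2 = std::min(std::max(y + dy, 0), Y - 1);
            const R_xlen_t rowb = y2 * sY + z2 * sZ;
            for (int x = 0; x < X; ++x, ++i) {
              const double m = sq[i] / h2;
              if (m > 30.0) continue;  // weight below 1e-13
              const double w = std::exp(-m);
              const int x2 = std::min(std::max(x + dx, 0), X - 1);
              wsum[i] += w;
              acc[i] += w * pv[x2 + rowb];
            }
          }
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < V; ++i)
    po[i] = wsum[i] > 0 ? acc[i] / wsum[i] : pv[i];
  out.attr("dim") = vd;
  return out;
}

// Binary erosion (op = 0) / dilation (op = 1) with a Euclidean ball of the
// given voxel radius.
// [[Rcpp::export(name = ".cq_morph")]]
IntegerVector cq_morph(IntegerVector mask, double radius, int op) {
  IntegerVector vd = mask.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int r = (int)std::floor(radius);
  std::vector<int> off;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius + 1e-9) {
          off.push_back(dx); off.push_back(dy); off.push_back(dz);
        }
  const int no = (int)off.size() / 3;
  IntegerVector out(mask.size());
  const int *pm = mask.begin();
  int *po = out.begin();
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  R_xlen_t oi = 0;
  for (int z = 0; z < Z; ++z) {
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x, ++oi) {
        int val = (op == 0) ? 1 : 0;
        for (int i = 0; i < no; ++i) {
          const int x2 = x + off[3 * i], y2 = y + off[3 * i + 1],
                    z2 = z + off[3 * i + 2];
          int m = 0;
          if (x2 >= 0 && x2 < X && y2 >= 0 && y2 < Y && z2 >= 0 && z2 < Z)
            m = pm[x2 + y2 * sY + z2 * sZ];
          if (op == 0 && m == 0) { val = 0; break; }
          if (op == 1 && m != 0) { val = 1; break; }
        }
        po[oi] = val;
      }
    }
  }
  out.attr("dim") = vd;
  return out;
}

// 6-connected component labels (0 stays background), labels ordered by
// discovery; sizes returned alongside.
// [[Rcpp::export(name = ".cq_label_cc")]]
List cq_label_cc(IntegerVector mask) {
  IntegerVector vd = mask.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  IntegerVector lab(mask.size());
  const int *pm = mask.begin();
  int *pl = lab.begin();
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  std::vector<R_xlen_t> stack;
  std::vector<double> sizes;
  int next = 0;
  const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  R_xlen_t oi = 0;
  for (int z = 0; z < Z; ++z) {
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x, ++oi) {
        if (pm[oi] == 0 || pl[oi] != 0) continue;
        ++next;
        double sz = 0;
        stack.clear();
        stack.push_back(oi);
        pl[oi] = next;
        while (!stack.empty()) {
          const R_xlen_t cur = stack.back();
          stack.pop_back();
          ++sz;
          const int cz = (int)(cur / sZ), cy = (int)((cur % sZ) / sY),
                    cx = (int)(cur % sY);
          for (int i = 0; i < 6; ++i) {
            const int x2 = cx + nb[i][0], y2 = cy + nb[i][1],
                      z2 = cz + nb[i][2];
            if (x2 < 0 || x2 >= X || y2 < 0 || y2 >= Y || z2 < 0 || z2 >= Z)
              continue;
            const R_xlen_t j = x2 + y2 * sY + z2 * sZ;
            if (pm[j] != 0 && pl[j] == 0) {
              pl[j] = next;
              stack.push_back(j);
            }
          }
        }
        sizes.push_back(sz);
      }
    }
  }
  lab.attr("dim") = vd;
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}

// Fill interior cavities: background 6-connected to the volume border stays
// background, every other voxel becomes foreground.
// [[Rcpp::export(name = ".cq_fill_holes")]]
IntegerVector cq_fill_holes(IntegerVector mask) {
  IntegerVector vd = mask.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  std::vector<char> outside(mask.size(), 0);
  const int *pm = mask.begin();
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x)
        if (x == 0 || y == 0 || z == 0 || x == X - 1 || y == Y - 1 ||
            z == Z - 1) {
          const R_xlen_t i = x + y * sY + z * sZ;
          if (pm[i] == 0 && !outside[i]) {
            outside[i] = 1;
            stack.push_back(i);
          }
        }
  const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!stack.empty()) {
    const R_xlen_t cur = stack.back();
    stack.pop_back();
    const int cz = (int)(cur / sZ), cy = (int)((cur % sZ) / sY),
              cx = (int)(cur % sY);
    for (int i = 0; i < 6; ++i) {
      const int x2 = cx + nb[i][0], y2 = cy + nb[i][1], z2 = cz + nb[i][2];
      if (x2 < 0 || x2 >= X || y2 < 0 || y2 >= Y || z2 < 0 || z2 >= Z)
        continue;
      const R_xlen_t j = x2 + y2 * sY + z2 * sZ;
      if (pm[j] == 0 && !outside[j]) {
        outside[j] = 1;
        stack.push_back(j);
      }
    }
  }
  IntegerVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = (pm[i] != 0 || !outside[i]) ? 1 : 0;
  out.attr("dim") = vd;
  return out;
}

// Row-wise empirical quantile (linear interpolation between order
// statistics, R's default type 7).
// [[Rcpp::export(name = ".cq_row_quantile")]]
NumericVector cq_row_quantile(NumericMatrix m, double p) {
  const int V = m.nrow(), n = m.ncol();
  NumericVector out(V);
  std::vector<double> buf(n);
  for (int v = 0; v < V; ++v) {
    for (int j = 0; j < n; ++j) buf[j] = m(v, j);
    std::sort(buf.begin(), buf.end());
    const double idx = p * (n - 1);
    const int lo = (int)std::floor(idx);
    const int hi = std::min(lo + 1, n - 1);
    const double frac = idx - lo;
    out[v] = buf[lo] * (1 - frac) + buf[hi] * frac;
  }
  return out;
}

// Assign each domain voxel with label 0 the label of the nearest labelled
// voxel (Euclidean distance in mm). Sites are visited in increasing label
// order so exact ties resolve to the smaller label.
// [[Rcpp::export(name = ".cq_nearest_label")]]
IntegerVector cq_nearest_label(IntegerVector labels, NumericVector spacing,
                               IntegerVector domain) {
  IntegerVector vd = labels.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const R_xlen_t sY = X, sZ = static_cast<R_xlen_t>(X) * Y;
  const int *pl = labels.begin();
  const int *pdom = domain.begin();
  // collect labelled sites; keep only boundary sites (some unlabelled
  // 6-neighbour) since the nearest labelled voxel to an external point is
  // always on the labelled set's boundary
  struct Site { int x, y, z, lab; };
  std::vector<Site> sites;
  const int nb[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const R_xlen_t i = x + y * sY + z * sZ;
        if (pl[i] == 0) continue;
        bool boundary = false;
        for (int k = 0; k < 6; ++k) {
          const int x2 = x + nb[k][0], y2 = y + nb[k][1], z2 = z + nb[k][2];
          if (x2 < 0 || x2 >= X || y2 < 0 || y2 >= Y || z2 < 0 || z2 >= Z) {
            boundary = true; break;
          }
          if (pl[x2 + y2 * sY + z2 * sZ] == 0) { boundary = true; break; }
        }
        if (boundary) sites.push_back({x, y, z, pl[i]});
      }
  if (sites.empty()) stop("no labelled voxels to extend from");
  std::stable_sort(sites.begin(), sites.end(),
                   [](const Site &a, const Site &b) { return a.lab < b.lab; });
  IntegerVector out = clone(labels);
  int *po = out.begin();
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  for (int z = 0; z < Z; ++z)
    for (int y = 0; y < Y; ++y)
      for (int x = 0; x < X; ++x) {
        const R_xlen_t i = x + y * sY + z * sZ;
        if (pl[i] != 0 || pdom[i] == 0) continue;
        double best = R_PosInf;
        int bl = 0;
        for (const Site &s : sites) {
          const double dx = (x - s.x) * sx, dy = (y - s.y) * sy,
                       dz = (z - s.z) * sz;
          const double d = dx * dx + dy * dy + dz * dz;
          if (d < best - 1e-12) { best = d; bl = s.lab; }
        }
        po[i] = bl;
      }
  out.attr("dim") = vd;
  return out;
}

// Fused leaky rectifier: returns the activation and the slope mask in
// one pass (saves two full-array scans per layer in the hot loop).
// [[Rcpp::export(name = ".cq_leaky")]]
List cq_leaky(NumericVector x, double alpha) {
  const R_xlen_t n = x.size();
  NumericVector y(n), m(n);
  const double *px = x.begin();
  double *py = y.begin(), *pm = m.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (px[i] >= 0) {
      py[i] = px[i];
      pm[i] = 1.0;
    } else {
      py[i] = alpha * px[i];
      pm[i] = alpha;
    }
  }
  y.attr("dim") = x.attr("dim");
  m.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["m"] = m);
}

// Weighted 2D histogram over bin indices (1-based), used by the Parzen
// joint-histogram estimator behind normalized mutual information.
// [[Rcpp::export(name = ".cq_hist2d_w")]]
NumericMatrix cq_hist2d_w(IntegerVector ix, IntegerVector iy, NumericVector w,
                          int nbins) {
  NumericMatrix h(nbins, nbins);
  const R_xlen_t n = ix.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const int a = ix[i] - 1, b = iy[i] - 1;
    if (a < 0 || a >= nbins || b < 0 || b >= nbins) continue;
    h(a, b) += w[i];
  }
  return h;
}
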