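#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Index helpers: all arrays are R column-major.
static inline R_xlen_t idx3(int i, int j, int k, int d1, int d2) {
  return (R_xlen_t)i + (R_xlen_t)d1 * ((R_xlen_t)j + (R_xlen_t)d2 * (R_xlen_t)k);
}

// Trilinear / nearest resampling of a 3D volume at normalized coordinates.
// grid: N x 3 matrix of normalized coords in [-1, 1], one row per output voxel
// in column-major order of the output dims. Normalized -1 maps to the centre of
// the first voxel, +1 to the centre of the last. Out-of-bounds samples read 0.
// [[Rcpp::export(name = ".cpp_resample3d")]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector dims,
                             NumericMatrix grid, bool nearest) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = grid.nrow();
  NumericVector out(n);
  const double h1 = (d1 - 1) / 2.0, h2 = (d2 - 1) / 2.0, h3 = (d3 - 1) / 2.0;
  const double c1 = h1, c2 = h2, c3 = h3; // 0-based centre
  for (R_xlen_t t = 0; t < n; ++t) {
    const double x = grid(t, 0) * h1 + c1;
    const double y = grid(t, 1) * h2 + c2;
    const double z = grid(t, 2) * h3 + c3;
    if (nearest) {
      const int i = (int)std::lround(x), j = (int)std::lround(y),
                k = (int)std::lround(z);
      out[t] = (i >= 0 && i < d1 && j >= 0 && j < d2 && k >= 0 && k < d3)
                   ? vol[idx3(i, j, k, d1, d2)]
                   : 0.0;
    } else {
      const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
                k0 = (int)std::floor(z);
      const double fx = x - i0, fy = y - j0, fz = z - k0;
      double acc = 0.0;
      for (int di = 0; di < 2; ++di)
        for (int dj = 0; dj < 2; ++dj)
          for (int dk = 0; dk < 2; ++dk) {
            const int i = i0 + di, j = j0 + dj, k = k0 + dk;
            if (i < 0 || i >= d1 || j < 0 || j >= d2 || k < 0 || k >= d3)
              continue;
            const double w = (di ? fx : 1.0 - fx) * (dj ? fy : 1.0 - fy) *
                             (dk ? fz : 1.0 - fz);
            acc += w * vol[idx3(i, j, k, d1, d2)];
          }
      out[t] = acc;
    }
  }
  return out;
}

// Fused rotation resampling: samples vol at M * n(v) for every output voxel
// without materializing the grid. M is 3x3 row-major on normalized coords.
// [[Rcpp::export(name = ".cpp_rotate_resample3d")]]
NumericVector cpp_rotate_resample3d(NumericVector vol, IntegerVector dims,
                                    NumericMatrix M, bool nearest) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double h1 = (d1 - 1) / 2.0, h2 = (d2 - 1) / 2.0, h3 = (d3 - 1) / 2.0;
  NumericVector out((R_xlen_t)d1 * d2 * d3);
  const double *pv = REAL(vol);
  double *po = REAL(out);
  const double m11 = M(0, 0), m12 = M(0, 1), m13 = M(0, 2);
  const double m21 = M(1, 0), m22 = M(1, 1), m23 = M(1, 2);
  const double m31 = M(2, 0), m32 = M(2, 1), m33 = M(2, 2);
  R_xlen_t t = 0;
  for (int k = 0; k < d3; ++k) {
    const double nz = h3 > 0 ? (k - h3) / h3 : 0.0;
    for (int j = 0; j < d2; ++j) {
      const double ny = h2 > 0 ? (j - h2) / h2 : 0.0;
      for (int i = 0; i < d1; ++i, ++t) {
        const double nx = h1 > 0 ? (i - h1) / h1 : 0.0;
        const double x = (m11 * nx + m12 * ny + m13 * nz) * h1 + h1;
        const double y = (m21 * nx + m22 * ny + m23 * nz) * h2 + h2;
        const double z = (m31 * nx + m32 * ny + m33 * nz) * h3 + h3;
        if (nearest) {
          const int ii = (int)std::lround(x), jj = (int)std::lround(y),
                    kk = (int)std::lround(z);
          po[t] = (ii >= 0 && ii < d1 && jj >= 0 && jj < d2 && kk >= 0 &&
                   kk < d3)
                      ? pv[idx3(ii, jj, kk, d1, d2)]
                      : 0.0;
        } else {
          const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
                    k0 = (int)std::floor(z);
          if (i0 >= 0 && i0 + 1 < d1 && j0 >= 0 && j0 + 1 < d2 && k0 >= 0 &&
              k0 + 1 < d3) {
            const double fx = x - i0, fy = y - j0, fz = z - k0;
            const double *b = pv + idx3(i0, j0, k0, d1, d2);
            const R_xlen_t s2 = d1, s3 = (R_xlen_t)d1 * d2;
            const double c00 = b[0] * (1 - fx) + b[1] * fx;
            const double c10 = b[s2] * (1 - fx) + b[s2 + 1] * fx;
            const double c01 = b[s3] * (1 - fx) + b[s3 + 1] * fx;
            const double c11 = b[s3 + s2] * (1 - fx) + b[s3 + s2 + 1] * fx;
            po[t] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                    (c01 * (1 - fy) + c11 * fy) * fz;
          } else {
            const double fx = x - i0, fy = y - j0, fz = z - k0;
            double acc = 0.0;
            for (int di = 0; di < 2; ++di)
              for (int dj = 0; dj < 2; ++dj)
                for (int dk = 0; dk < 2; ++dk) {
                  const int ii = i0 + di, jj = j0 + dj, kk = k0 + dk;
                  if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 ||
                      kk >= d3)
                    continue;
                  acc += (di ? fx : 1.0 - fx) * (dj ? fy : 1.0 - fy) *
                         (dk ? fz : 1.0 - fz) * pv[idx3(ii, jj, kk, d1, d2)];
                }
            po[t] = acc;
          }
        }
      }
    }
  }
  return out;
}

// 2D warp: out(p) = img(p + field(p)); field in pixels, component 1 along rows.
// [[Rcpp::export(name = ".cpp_warp2d")]]
NumericVector cpp_warp2d(NumericVector img, IntegerVector dims,
                         NumericVector field, bool nearest) {
  const int H = dims[0], W = dims[1];
  const R_xlen_t n = (R_xlen_t)H * W;
  NumericVector out(n);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const R_xlen_t t = (R_xlen_t)i + (R_xlen_t)H * j;
      const double x = i + field[t];
      const double y = j + field[t + n];
      if (nearest) {
        const int ii = (int)std::lround(x), jj = (int)std::lround(y);
        out[t] = (ii >= 0 && ii < H && jj >= 0 && jj < W)
                     ? img[(R_xlen_t)ii + (R_xlen_t)H * jj]
                     : 0.0;
      } else {
        const int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
        const double fx = x - i0, fy = y - j0;
        double acc = 0.0;
        for (int di = 0; di < 2; ++di)
          for (int dj = 0; dj < 2; ++dj) {
            const int ii = i0 + di, jj = j0 + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            acc += (di ? fx : 1.0 - fx) * (dj ? fy : 1.0 - fy) *
                   img[(R_xlen_t)ii + (R_xlen_t)H * jj];
          }
        out[t] = acc;
      }
    }
  return out;
}

// Backward of cpp_warp2d (bilinear) w.r.t. the displacement field:
// gfield(p) = gout(p) * d img(p + field(p)) / d(field components).
// [[Rcpp::export(name = ".cpp_warp2d_bwd")]]
NumericVector cpp_warp2d_bwd(NumericVector img, IntegerVector dims,
                             NumericVector field, NumericVector gout) {
  const int H = dims[0], W = dims[1];
  const R_xlen_t n = (R_xlen_t)H * W;
  NumericVector gfield(2 * n);
  auto at = [&](int i, int j) -> double {
    return (i >= 0 && i < H && j >= 0 && j < W)
               ? img[(R_xlen_t)i + (R_xlen_t)H * j]
               : 0.0;
  };
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const R_xlen_t t = (R_xlen_t)i + (R_xlen_t)H * j;
      const double x = i + field[t];
      const double y = j + field[t + n];
      const int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
      const double fx = x - i0, fy = y - j0;
      const double v00 = at(i0, j0), v10 = at(i0 + 1, j0);
      const double v01 = at(i0, j0 + 1), v11 = at(i0 + 1, j0 + 1);
      const double dx = (v10 - v00) * (1.0 - fy) + (v11 - v01) * fy;
      const double dy = (v01 - v00) * (1.0 - fx) + (v11 - v10) * fx;
      gfield[t] = gout[t] * dx;
      gfield[t + n] = gout[t] * dy;
    }
  return gfield;
}

// ---- 3D convolution -------------------------------------------------------
// x: (D, H, W, Ci), w: (k, k, k, Ci, Co), y: (Do, Ho, Wo, Co); zero padding.

static inline int outdim(int d, int k, int stride, int pad) {
  return (d + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, int k, int ci, int co,
                             NumericVector b, int stride, int pad) {
  const int D = xd[0], H = xd[1], W = xd[2];
  const int Do = outdim(D, k, stride, pad), Ho = outdim(H, k, stride, pad),
            Wo = outdim(W, k, stride, pad);
  NumericVector y((R_xlen_t)Do * Ho * Wo * co);
  const double *px = REAL(x), *pw = REAL(w);
  double *py = REAL(y);
  for (int oc = 0; oc < co; ++oc)
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const int id0_base = -pad, ih0 = oh * stride - pad,
                  iw0 = ow * stride - pad;
        const int kh_lo = std::max(0, -ih0), kh_hi = std::min(k, H - ih0);
        const int kw_lo = std::max(0, -iw0), kw_hi = std::min(k, W - iw0);
        double *yrow =
            py + (R_xlen_t)Do * ((R_xlen_t)oh +
                                 (R_xlen_t)Ho * ((R_xlen_t)ow +
                                                 (R_xlen_t)Wo * oc));
        for (int od = 0; od < Do; ++od) yrow[od] = b[oc];
        // accumulate over output depth (vectorizable inner loop)
        for (int ic = 0; ic < ci; ++ic) {
          const double *xc = px + (R_xlen_t)D * H * W * ic;
          const double *wc =
              pw + (R_xlen_t)k * k * k * ((R_xlen_t)ic + (R_xlen_t)ci * oc);
          for (int kw = kw_lo; kw < kw_hi; ++kw)
            for (int kh = kh_lo; kh < kh_hi; ++kh) {
              const double *xplane =
                  xc + (R_xlen_t)D * ((R_xlen_t)(ih0 + kh) +
                                      (R_xlen_t)H * (iw0 + kw));
              const double *wrow = wc + (R_xlen_t)k * (kh + (R_xlen_t)k * kw);
              for (int kd = 0; kd < k; ++kd) {
                const double wv = wrow[kd];
                if (wv == 0.0) continue;
                const int base = id0_base + kd;
                int od_lo = base < 0 ? (-base + stride - 1) / stride : 0;
                int od_hi = std::min(Do, (D - 1 - base) / stride + 1);
                const double *xr = xplane + base;
                for (int od = od_lo; od < od_hi; ++od)
                  yrow[od] += wv * xr[od * stride];
              }
            }
        }
      }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector xd, NumericVector w, int k,
                    int ci, int co, NumericVector gy, int stride, int pad) {
  const int D = xd[0], H = xd[1], W = xd[2];
  const int Do = outdim(D, k, stride, pad), Ho = outdim(H, k, stride, pad),
            Wo = outdim(W, k, stride, pad);
  NumericVector gx((R_xlen_t)D * H * W * ci);
  NumericVector gw(w.size());
  NumericVector gb(co);
  const double *px = REAL(x), *pw = REAL(w), *pgy = REAL(gy);
  double *pgx = REAL(gx), *pgw = REAL(gw);
  for (int oc = 0; oc < co; ++oc)
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh) {
        const int ih0 = oh * stride - pad, iw0 = ow * stride - pad;
        const int kh_lo = std::max(0, -ih0), kh_hi = std::min(k, H - ih0);
        const int kw_lo = std::max(0, -iw0), kw_hi = std::min(k, W - iw0);
        const double *gyrow =
            pgy + (R_xlen_t)Do * ((R_xlen_t)oh +
                                  (R_xlen_t)Ho * ((R_xlen_t)ow +
                                                  (R_xlen_t)Wo * oc));
        for (int od = 0; od < Do; ++od) gb[oc] += gyrow[od];
        for (int ic = 0; ic < ci; ++ic) {
          const double *xc = px + (R_xlen_t)D * H * W * ic;
          double *gxc = pgx + (R_xlen_t)D * H * W * ic;
          const double *wc =
              pw + (R_xlen_t)k * k * k * ((R_xlen_t)ic + (R_xlen_t)ci * oc);
          double *gwc =
              pgw + (R_xlen_t)k * k * k * ((R_xlen_t)ic + (R_xlen_t)ci * oc);
          for (int kw = kw_lo; kw < kw_hi; ++kw)
            for (int kh = kh_lo; kh < kh_hi; ++kh) {
              const R_xlen_t poff =
                  (R_xlen_t)D * ((R_xlen_t)(ih0 + kh) +
                                 (R_xlen_t)H * (iw0 + kw));
              const double *xplane = xc + poff;
              double *gxplane = gxc + poff;
              const R_xlen_t woff = (R_xlen_t)k * (kh + (R_xlen_t)k * kw);
              const double *wrow = wc + woff;
              double *gwrow = gwc + woff;
              for (int kd = 0; kd < k; ++kd) {
                const int base = -pad + kd;
                int od_lo = base < 0 ? (-base + stride - 1) / stride : 0;
                int od_hi = std::min(Do, (D - 1 - base) / stride + 1);
                const double *xr = xplane + base;
                double *gxr = gxplane + base;
                const double wv = wrow[kd];
                double gwacc = 0.0;
                for (int od = od_lo; od < od_hi; ++od) {
                  const double g = gyrow[od];
                  gxr[od * stride] += g * wv;
                  gwacc += g * xr[od * stride];
                }
                gwrow[kd] += gwacc;
              }
            }
        }
      }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---- 2D convolution -------------------------------------------------------
// x: (H, W, Ci), w: (k, k, Ci, Co), y: (Ho, Wo, Co); zero padding.

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector w, int k, int ci, int co,
                             NumericVector b, int stride, int pad) {
  const int H = xd[0], W = xd[1];
  const int Ho = outdim(H, k, stride, pad), Wo = outdim(W, k, stride, pad);
  NumericVector y((R_xlen_t)Ho * Wo * co);
  const double *px = REAL(x), *pw = REAL(w);
  double *py = REAL(y);
  for (int oc = 0; oc < co; ++oc)
    for (int ow = 0; ow < Wo; ++ow) {
      const int iw0 = ow * stride - pad;
      const int kw_lo = std::max(0, -iw0), kw_hi = std::min(k, W - iw0);
      double *yrow = py + (R_xlen_t)Ho * ((R_xlen_t)ow + (R_xlen_t)Wo * oc);
      for (int oh = 0; oh < Ho; ++oh) yrow[oh] = b[oc];
      for (int ic = 0; ic < ci; ++ic) {
        const double *xc = px + (R_xlen_t)H * W * ic;
        const double *wc =
            pw + (R_xlen_t)k * k * ((R_xlen_t)ic + (R_xlen_t)ci * oc);
        for (int kw = kw_lo; kw < kw_hi; ++kw) {
          const double *xcol = xc + (R_xlen_t)H * (iw0 + kw);
          const double *wcol = wc + (R_xlen_t)k * kw;
          for (int kh = 0; kh < k; ++kh) {
            const double wv = wcol[kh];
            if (wv == 0.0) continue;
            const int base = -pad + kh;
            int oh_lo = base < 0 ? (-base + stride - 1) / stride : 0;
            int oh_hi = std::min(Ho, (H - 1 - base) / stride + 1);
            const double *xr = xcol + base;
            for (int oh = oh_lo; oh < oh_hi; ++oh)
              yrow[oh] += wv * xr[oh * stride];
          }
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, IntegerVector xd, NumericVector w, int k,
                    int ci, int co, NumericVector gy, int stride, int pad) {
  const int H = xd[0], W = xd[1];
  const int Ho = outdim(H, k, stride, pad), Wo = outdim(W, k, stride, pad);
  NumericVector gx((R_xlen_t)H * W * ci);
  NumericVector gw(w.size());
  NumericVector gb(co);
  const double *px = REAL(x), *pw = REAL(w), *pgy = REAL(gy);
  double *pgx = REAL(gx), *pgw = REAL(gw);
  for (int oc = 0; oc < co; ++oc)
    for (int ow = 0; ow < Wo; ++ow) {
      const int iw0 = ow * stride - pad;
      const int kw_lo = std::max(0, -iw0), kw_hi = std::min(k, W - iw0);
      const double *gyrow =
          pgy + (R_xlen_t)Ho * ((R_xlen_t)ow + (R_xlen_t)Wo * oc);
      for (int oh = 0; oh < Ho; ++oh) gb[oc] += gyrow[oh];
      for (int ic = 0; ic < ci; ++ic) {
        const double *xc = px + (R_xlen_t)H * W * ic;
        double *gxc = pgx + (R_xlen_t)H * W * ic;
        const double *wc =
            pw + (R_xlen_t)k * k * ((R_xlen_t)ic + (R_xlen_t)ci * oc);
        double *gwc =
            pgw + (R_xlen_t)k * k * ((R_xlen_t)ic + (R_xlen_t)ci * oc);
        for (int kw = kw_lo; kw < kw_hi; ++kw) {
          const R_xlen_t coff = (R_xlen_t)H * (iw0 + kw);
          const double *xcol = xc + coff;
          double *gxcol = gxc + coff;
          for (int kh = 0; kh < k; ++kh) {
            const int base = -pad + kh;
            int oh_lo = base < 0 ? (-base + stride - 1) / stride : 0;
            int oh_hi = std::min(Ho, (H - 1 - base) / stride + 1);
            const double wv = wc[(R_xlen_t)k * kw + kh];
            const double *xr = xcol + base;
            double *gxr = gxcol + base;
            double gwacc = 0.0;
            for (int oh = oh_lo; oh < oh_hi; ++oh) {
              const double g = gyrow[oh];
              gxr[oh * stride] += g * wv;
              gwacc += g * xr[oh * stride];
            }
            gwc[(R_xlen_t)k * kw + kh] += gwacc;
          }
        }
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Exact 1D squared-distance transform (Felzenszwalb & Huttenlocher), used
// row/column-wise to build exact Euclidean distance maps for mask softening.
// f: input costs (0 on sites, large elsewhere); returns lower envelope.
// [[Rcpp::export(name = ".cpp_edt1d")]]
NumericVector cpp_edt1d(NumericVector f) {
  const int n = f.size();
  NumericVector d(n);
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kk = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[kk]] + v[kk] * (double)v[kk])) /
               (2.0 * q - 2.0 * v[kk]);
    while (s <= z[kk]) {
      --kk;
      s = ((f[q] + q * (double)q) - (f[v[kk]] + v[kk] * (double)v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INFINITY;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (double)(q - v[kk]) + f[v[kk]];
  }
  return d;
}
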