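// Low-level numerical kernels: 3D convolution (im2col + BLAS GEMM),
// pooling, PReLU, trilinear warping/resampling, and box filtering.
//
// Array layout conventions (match the R side):
//   volumes            : (D, H, W)            column-major, D fastest
//   activation tensors : (D, H, W, C, B)
//   conv weights       : matrix (k^3 * Cin, Cout); row = tap + k^3 * c
//                        with tap = od + k*oh + k*k*ow
// Convolutions are stride-1, odd kernel, zero padding (k-1)/2 (same size).
// Pooling is fixed kernel 3, stride 2, padding 1; padding is excluded
// from max/avg windows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_pool_dim(int n) { return (n - 1) / 2 + 1; }

// Gather one sample's im2col block.  `dst` points at the sample's first
// row inside a shared (B*n_vox x k^3*C) column matrix whose columns are
// `colstride` elements apart.
static void im2col_strided(const double* x, int D, int H, int W, int C,
                           int k, double* dst0, size_t colstride) {
  const int p = (k - 1) / 2;
  const int n_vox = D * H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * n_vox;
    for (int ow = 0; ow < k; ++ow) {
      for (int oh = 0; oh < k; ++oh) {
        for (int od = 0; od < k; ++od) {
          const int tap = od + k * oh + k * k * ow;
          double* dst = dst0 + colstride * ((size_t)tap + (size_t)k * k * k * c);
          const int sd_off = od - p, sh_off = oh - p, sw_off = ow - p;
          for (int iw = 0; iw < W; ++iw) {
            const int sw = iw + sw_off;
            double* dw = dst + (size_t)D * H * iw;
            if (sw < 0 || sw >= W) {
              std::fill(dw, dw + (size_t)D * H, 0.0);
              continue;
            }
            for (int ih = 0; ih < H; ++ih) {
              const int sh = ih + sh_off;
              double* dh = dw + (size_t)D * ih;
              if (sh < 0 || sh >= H) {
                std::fill(dh, dh + D, 0.0);
                continue;
              }
              const double* src = xc + (size_t)D * (sh + (size_t)H * sw);
              const int d0 = std::max(0, -sd_off);
              const int d1 = std::min(D, D - sd_off);
              if (d0 > 0) std::fill(dh, dh + d0, 0.0);
              if (d1 > d0) std::copy(src + d0 + sd_off, src + d1 + sd_off, dh + d0);
              if (d1 < D) std::fill(dh + std::max(d1, d0), dh + D, 0.0);
            }
          }
        }
      }
    }
  }
}

// Scatter-add one sample's dcol block (same strided layout) into dx.
static void col2im_add_strided(const double* src0, size_t colstride, int D,
                               int H, int W, int C, int k, double* dx) {
  const int p = (k - 1) / 2;
  const int n_vox = D * H * W;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)c * n_vox;
    for (int ow = 0; ow < k; ++ow) {
      for (int oh = 0; oh < k; ++oh) {
        for (int od = 0; od < k; ++od) {
          const int tap = od + k * oh + k * k * ow;
          const double* src = src0 + colstride * ((size_t)tap + (size_t)k * k * k * c);
          const int sd_off = od - p, sh_off = oh - p, sw_off = ow - p;
          for (int iw = 0; iw < W; ++iw) {
            const int sw = iw + sw_off;
            if (sw < 0 || sw >= W) continue;
            for (int ih = 0; ih < H; ++ih) {
              const int sh = ih + sh_off;
              if (sh < 0 || sh >= H) continue;
              double* dstp = xc + (size_t)D * (sh + (size_t)H * sw);
              const double* sp = src + (size_t)D * (ih + (size_t)H * iw);
              const int d0 = std::max(0, -sd_off);
              const int d1 = std::min(D, D - sd_off);
              for (int id = d0; id < d1; ++id) dstp[id + sd_off] += sp[id];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, IntegerVector xdim,
                            NumericMatrix w, NumericVector bias, int k) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const int n_vox = D * H * W;
  const int Cout = w.ncol();
  const int kc = k * k * k * C;
  if (w.nrow() != kc) stop("conv weight shape mismatch");
  NumericVector out((size_t)n_vox * Cout * B);
  arma::mat wm(w.begin(), kc, Cout, false, true);
  arma::rowvec brow(bias.begin(), Cout);
  arma::mat col(n_vox, kc);
  for (int b = 0; b < B; ++b) {
    im2col_strided(x.begin() + (size_t)b * n_vox * C, D, H, W, C, k,
                   col.memptr(), (size_t)n_vox);
    arma::mat ym(out.begin() + (size_t)b * n_vox * Cout, n_vox, Cout,
                 false, true);
    ym = col * wm;
    ym.each_row() += brow;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, IntegerVector xdim, NumericMatrix w,
                   NumericVector dy, int k, bool need_dx) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const int n_vox = D * H * W;
  const int Cout = w.ncol();
  const int kc = k * k * k * C;
  NumericVector dx(need_dx ? (size_t)n_vox * C * B : 0);
  NumericMatrix dw(kc, Cout);
  NumericVector db(Cout);
  arma::mat wm(w.begin(), kc, Cout, false, true);
  arma::mat dwm(dw.begin(), kc, Cout, false, true);
  arma::vec dbm(db.begin(), Cout, false, true);
  arma::mat col(n_vox, kc);
  arma::mat dcol(n_vox, kc);
  for (int b = 0; b < B; ++b) {
    im2col_strided(x.begin() + (size_t)b * n_vox * C, D, H, W, C, k,
                   col.memptr(), (size_t)n_vox);
    arma::mat dym(const_cast<double*>(dy.begin()) + (size_t)b * n_vox * Cout,
                  n_vox, Cout, false, true);
    dwm += col.t() * dym;
    dbm += arma::sum(dym, 0).t();
    if (need_dx) {
      dcol = dym * wm.t();
      col2im_add_strided(dcol.memptr(), (size_t)n_vox, D, H, W, C, k,
                         dx.begin() + (size_t)b * n_vox * C);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Pooling, kernel 3 / stride 2 / pad 1.  type 0 = max, 1 = average.
// [[Rcpp::export]]
List cpp_pool3d_fw(NumericVector x, IntegerVector xdim, int type) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const int Do = out_pool_dim(D), Ho = out_pool_dim(H), Wo = out_pool_dim(W);
  const size_t n_in = (size_t)D * H * W;
  const size_t n_out = (size_t)Do * Ho * Wo;
  NumericVector y(n_out * C * B);
  IntegerVector idx(type == 0 ? n_out * C * B : 0);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + n_in * ((size_t)c + (size_t)C * b);
      const size_t obase = n_out * ((size_t)c + (size_t)C * b);
      for (int ow = 0; ow < Wo; ++ow) {
        const int w0 = std::max(0, 2 * ow - 1), w1 = std::min(W, 2 * ow + 2);
        for (int oh = 0; oh < Ho; ++oh) {
          const int h0 = std::max(0, 2 * oh - 1), h1 = std::min(H, 2 * oh + 2);
          for (int od = 0; od < Do; ++od) {
            const int d0 = std::max(0, 2 * od - 1), d1 = std::min(D, 2 * od + 2);
            double best = -std::numeric_limits<double>::infinity();
            double acc = 0.0;
            int besti = -1, cnt = 0;
            for (int iw = w0; iw < w1; ++iw)
              for (int ih = h0; ih < h1; ++ih)
                for (int id = d0; id < d1; ++id) {
                  const size_t li = id + (size_t)D * (ih + (size_t)H * iw);
                  const double v = xs[li];
                  if (type == 0) {
                    if (v > best) { best = v; besti = (int)li; }
                  } else { acc += v; ++cnt; }
                }
            const size_t oi = obase + od + (size_t)Do * (oh + (size_t)Ho * ow);
            if (type == 0) { y[oi] = best; idx[oi] = besti; }
            else y[oi] = acc / cnt;
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx,
                      _["odim"] = IntegerVector::create(Do, Ho, Wo, C, B));
}

// [[Rcpp::export]]
NumericVector cpp_pool3d_bw(NumericVector dy, IntegerVector idx,
                            IntegerVector xdim, int type) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3], B = xdim[4];
  const int Do = out_pool_dim(D), Ho = out_pool_dim(H), Wo = out_pool_dim(W);
  const size_t n_in = (size_t)D * H * W;
  const size_t n_out = (size_t)Do * Ho * Wo;
  NumericVector dx(n_in * C * B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      double* dxs = dx.begin() + n_in * ((size_t)c + (size_t)C * b);
      const size_t obase = n_out * ((size_t)c + (size_t)C * b);
      for (int ow = 0; ow < Wo; ++ow) {
        const int w0 = std::max(0, 2 * ow - 1), w1 = std::min(W, 2 * ow + 2);
        for (int oh = 0; oh < Ho; ++oh) {
          const int h0 = std::max(0, 2 * oh - 1), h1 = std::min(H, 2 * oh + 2);
          for (int od = 0; od < Do; ++od) {
            const int d0 = std::max(0, 2 * od - 1), d1 = std::min(D, 2 * od + 2);
            const size_t oi = obase + od + (size_t)Do * (oh + (size_t)Ho * ow);
            const double g = dy[oi];
            if (type == 0) {
              dxs[idx[oi]] += g;
            } else {
              const int cnt = (d1 - d0) * (h1 - h0) * (w1 - w0);
              const double gg = g / cnt;
              for (int iw = w0; iw < w1; ++iw)
                for (int ih = h0; ih < h1; ++ih)
                  for (int id = d0; id < d1; ++id)
                    dxs[id + (size_t)D * (ih + (size_t)H * iw)] += gg;
            }
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_prelu_fw(NumericVector x, IntegerVector xdim,
                           NumericVector a) {
  const size_t n_sp = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3], B = xdim[4];
  NumericVector y(x.size());
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c];
      const size_t off = n_sp * ((size_t)c + (size_t)C * b);
      for (size_t i = 0; i < n_sp; ++i) {
        const double v = x[off + i];
        y[off + i] = v > 0 ? v : ac * v;
      }
    }
  return y;
}

// [[Rcpp::export]]
List cpp_prelu_bw(NumericVector x, IntegerVector xdim, NumericVector a,
                  NumericVector dy) {
  const size_t n_sp = (size_t)xdim[0] * xdim[1] * xdim[2];
  const int C = xdim[3], B = xdim[4];
  NumericVector dx(x.size());
  NumericVector da(C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double ac = a[c];
      const size_t off = n_sp * ((size_t)c + (size_t)C * b);
      double acc = 0.0;
      for (size_t i = 0; i < n_sp; ++i) {
        const double v = x[off + i], g = dy[off + i];
        if (v > 0) dx[off + i] = g;
        else { dx[off + i] = ac * g; acc += g * v; }
      }
      da[c] += acc;
    }
  return List::create(_["dx"] = dx, _["da"] = da);
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear (or nearest-neighbour) sampling of `vol` at voxel + displacement.
// field layout (D,H,W,3), components ordered (x, y, z) where x displaces the
// third array index (W), y the second (H), z the first (D).  Out-of-range
// sample coordinates are clamped (border replication).
// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector vol, IntegerVector dim,
                       NumericVector field, bool nearest) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const size_t n = (size_t)D * H * W;
  NumericVector out(n);
  for (int iw = 0; iw < W; ++iw)
    for (int ih = 0; ih < H; ++ih)
      for (int id = 0; id < D; ++id) {
        const size_t li = id + (size_t)D * (ih + (size_t)H * iw);
        const double ux = field[li];
        const double uy = field[li + n];
        const double uz = field[li + 2 * n];
        double z = clampd(id + uz, 0, D - 1);
        double y = clampd(ih + uy, 0, H - 1);
        double x = clampd(iw + ux, 0, W - 1);
        if (nearest) {
          const int zi = (int)std::floor(z + 0.5);
          const int yi = (int)std::floor(y + 0.5);
          const int xi = (int)std::floor(x + 0.5);
          out[li] = vol[zi + (size_t)D * (yi + (size_t)H * xi)];
        } else {
          const int z0 = (int)std::floor(z), y0 = (int)std::floor(y),
                    x0 = (int)std::floor(x);
          const int z1 = std::min(z0 + 1, D - 1), y1 = std::min(y0 + 1, H - 1),
                    x1 = std::min(x0 + 1, W - 1);
          const double fz = z - z0, fy = y - y0, fx = x - x0;
          double v = 0.0;
          for (int cz = 0; cz < 2; ++cz)
            for (int cy = 0; cy < 2; ++cy)
              for (int cx = 0; cx < 2; ++cx) {
                const double wgt = (cz ? fz : 1 - fz) * (cy ? fy : 1 - fy) *
                                   (cx ? fx : 1 - fx);
                if (wgt == 0) continue;
                v += wgt * vol[(cz ? z1 : z0) +
                               (size_t)D * ((cy ? y1 : y0) +
                                            (size_t)H * (cx ? x1 : x0))];
              }
          out[li] = v;
        }
      }
  return out;
}

// Resample on a new lattice: out voxel i samples source at i*scale + offset
// per axis (0-based coordinates), trilinear, border clamped.
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           IntegerVector odim, NumericVector scale,
                           NumericVector offset) {
  const int D = dim[0], H = dim[1], W = dim[2];
  const int Do = odim[0], Ho = odim[1], Wo = odim[2];
  NumericVector out((size_t)Do * Ho * Wo);
  for (int iw = 0; iw < Wo; ++iw)
    for (int ih = 0; ih < Ho; ++ih)
      for (int id = 0; id < Do; ++id) {
        double z = clampd(id * scale[0] + offset[0], 0, D - 1);
        double y = clampd(ih * scale[1] + offset[1], 0, H - 1);
        double x = clampd(iw * scale[2] + offset[2], 0, W - 1);
        const int z0 = (int)std::floor(z), y0 = (int)std::floor(y),
                  x0 = (int)std::floor(x);
        const int z1 = std::min(z0 + 1, D - 1), y1 = std::min(y0 + 1, H - 1),
                  x1 = std::min(x0 + 1, W - 1);
        const double fz = z - z0, fy = y - y0, fx = x - x0;
        double v = 0.0;
        for (int cz = 0; cz < 2; ++cz)
          for (int cy = 0; cy < 2; ++cy)
            for (int cx = 0; cx < 2; ++cx) {
              const double wgt = (cz ? fz : 1 - fz) * (cy ? fy : 1 - fy) *
                                 (cx ? fx : 1 - fx);
              if (wgt == 0) continue;
              v += wgt * vol[(cz ? z1 : z0) +
                             (size_t)D * ((cy ? y1 : y0) +
                                          (size_t)H * (cx ? x1 : x0))];
            }
        out[id + (size_t)Do * (ih + (size_t)Ho * iw)] = v;
      }
  return out;
}

// Exact 3D box average over a (2r+1)^3 neighbourhood with border
// replication, via an integral image on the replicate-padded array.
// [[Rcpp::export]]
NumericVector cpp_boxfilter3d(NumericVector vol, IntegerVector dim, int r) {
  const int D = dim[0], H = dim[1], W = dim[2];
  if (r == 0) return clone(vol);
  const int Dp = D + 2 * r, Hp = H + 2 * r, Wp = W + 2 * r;
  std::vector<double> pad((size_t)Dp * Hp * Wp);
  for (int iw = 0; iw < Wp; ++iw) {
    const int sw = std::min(std::max(iw - r, 0), W - 1);
    for (int ih = 0; ih < Hp; ++ih) {
      const int sh = std::min(std::max(ih - r, 0), H - 1);
      for (int id = 0; id < Dp; ++id) {
        const int sd = std::min(std::max(id - r, 0), D - 1);
        pad[id + (size_t)Dp * (ih + (size_t)Hp * iw)] =
            vol[sd + (size_t)D * (sh + (size_t)H * sw)];
      }
    }
  }
  // cumulative sums along each axis
  for (int iw = 0; iw < Wp; ++iw)
    for (int ih = 0; ih < Hp; ++ih)
      for (int id = 1; id < Dp; ++id)
        pad[id + (size_t)Dp * (ih + (size_t)Hp * iw)] +=
            pad[id - 1 + (size_t)Dp * (ih + (size_t)Hp * iw)];
  for (int iw = 0; iw < Wp; ++iw)
    for (int ih = 1; ih < Hp; ++ih)
      for (int id = 0; id < Dp; ++id)
        pad[id + (size_t)Dp * (ih + (size_t)Hp * iw)] +=
            pad[id + (size_t)Dp * (ih - 1 + (size_t)Hp * iw)];
  for (int iw = 1; iw < Wp; ++iw)
    for (int ih = 0; ih < Hp; ++ih)
      for (int id = 0; id < Dp; ++id)
        pad[id + (size_t)Dp * (ih + (size_t)Hp * iw)] +=
            pad[id + (size_t)Dp * (ih + (size_t)Hp * (iw - 1))];
  const double nrm = 1.0 / ((2 * r + 1) * (2 * r + 1) * (2 * r + 1));
  NumericVector out((size_t)D * H * W);
  auto S = [&](int a, int b, int c) -> double {
    if (a < 0 || b < 0 || c < 0) return 0.0;
    return pad[a + (size_t)Dp * (b + (size_t)Hp * c)];
  };
  for (int iw = 0; iw < W; ++iw)
    for (int ih = 0; ih < H; ++ih)
      for (int id = 0; id < D; ++id) {
        const int d1 = id + 2 * r, h1 = ih + 2 * r, w1 = iw + 2 * r;
        const int d0 = id - 1, h0 = ih - 1, w0 = iw - 1;
        const double s = S(d1, h1, w1) - S(d0, h1, w1) - S(d1, h0, w1) -
                         S(d1, h1, w0) + S(d0, h0, w1) + S(d0, h1, w0) +
                         S(d1, h0, w0) - S(d0, h0, w0);
        out[id + (size_t)D * (ih + (size_t)H * iw)] = s * nrm;
      }
  return out;
}
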