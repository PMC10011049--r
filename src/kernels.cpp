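#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Feature maps are R arrays with dim (n1, n2, n3, C), column-major, so the
// first spatial axis is fastest and channels are outermost. Convolution
// weights have dim (k, k, k, Cin, Cout). All convolutions are "same"
// (zero padding (k-1)/2) with stride 1, which is what the encoder-decoder
// uses; resolution changes happen only in pooling / upsampling layers.

static inline int idx4(int i, int j, int z, int c, int n1, int n2, int n3) {
  return i + n1 * (j + n2 * (z + n3 * c));
}

// Fill the im2col block for output z-planes [z0, z0+zs). col is laid out
// (n1*n2*zs) x (k^3*Cin): one column per kernel offset/input channel, so the
// inner copy over the fastest spatial axis is contiguous. Column order
// matches the weight layout (k, k, k, Cin).
static void im2col_slab(const double *x, arma::mat &col,
                        int n1, int n2, int n3, int cin,
                        int k, int pad, int z0, int zs) {
  const int plane = n1 * n2;
  for (int c = 0; c < cin; ++c) {
    for (int dk = 0; dk < k; ++dk) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int r = di + k * (dj + k * (dk + k * c));
          double *cp = col.colptr(r);
          const int ilo = std::max(0, pad - di);
          const int ihi = std::min(n1, n1 + pad - di);
          for (int zz = 0; zz < zs; ++zz) {
            const int zi = z0 + zz + dk - pad;
            if (zi < 0 || zi >= n3) {
              std::fill(cp + zz * plane, cp + (zz + 1) * plane, 0.0);
              continue;
            }
            for (int j = 0; j < n2; ++j) {
              double *dst = cp + zz * plane + j * n1;
              const int ji = j + dj - pad;
              if (ji < 0 || ji >= n2) { std::fill(dst, dst + n1, 0.0); continue; }
              if (ilo > 0) std::fill(dst, dst + ilo, 0.0);
              if (ihi < n1) std::fill(dst + ihi, dst + n1, 0.0);
              if (ihi > ilo)
                std::copy(x + idx4(ilo + di - pad, ji, zi, c, n1, n2, n3),
                          x + idx4(ihi + di - pad, ji, zi, c, n1, n2, n3), dst + ilo);
            }
          }
        }
      }
    }
  }
}

static int slab_size(int rows, int plane, int n3) {
  // cap the transient im2col buffer at ~64 MB
  double maxcols = 64.0 * 1024 * 1024 / 8.0 / rows;
  int zs = (int)std::floor(maxcols / plane);
  if (zs < 1) zs = 1;
  if (zs > n3) zs = n3;
  return zs;
}

// shared forward core: out (pre-allocated, vox*cout) = conv(x, w) + bias
static void conv_core_fwd(const double *x, const double *W2, const double *bias,
                          double *out, int n1, int n2, int n3, int cin,
                          int k, int cout) {
  const int pad = (k - 1) / 2;
  const int rows = k * k * k * cin;
  const int plane = n1 * n2;
  const R_xlen_t vox = static_cast<R_xlen_t>(plane) * n3;
  const int zs0 = slab_size(rows, plane, n3);
  arma::mat col(static_cast<size_t>(plane) * zs0, rows);
  arma::mat W2m(const_cast<double *>(W2), rows, cout, false, true);
  for (int z0 = 0; z0 < n3; z0 += zs0) {
    const int zs = std::min(zs0, n3 - z0);
    arma::mat colv(col.memptr(), static_cast<size_t>(plane) * zs, rows, false, true);
    im2col_slab(x, colv, n1, n2, n3, cin, k, pad, z0, zs);
    arma::mat outm = colv * W2m; // (plane*zs) x cout
    for (int o = 0; o < cout; ++o) {
      double *dst = out + static_cast<R_xlen_t>(o) * vox + static_cast<R_xlen_t>(z0) * plane;
      const double *src = outm.colptr(o);
      const double b = bias ? bias[o] : 0.0;
      const int n = plane * zs;
      for (int t = 0; t < n; ++t) dst[t] = src[t] + b;
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             IntegerVector xdim, int k, int cout) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], cin = xdim[3];
  const int rows = k * k * k * cin;
  NumericVector out(static_cast<R_xlen_t>(n1) * n2 * n3 * cout);
  conv_core_fwd(x.begin(), w.begin(), bias.begin(), out.begin(),
                n1, n2, n3, cin, k, cout);
  out.attr("dim") = IntegerVector::create(n1, n2, n3, cout);
  return out;
}

// Backward pass. dW and db come from the im2col representation; dx is the
// "same" convolution of dout with the spatially flipped, channel-transposed
// kernel (exact for odd k with symmetric zero padding).
// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dout,
                    IntegerVector xdim, int k, int cout) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], cin = xdim[3];
  const int pad = (k - 1) / 2;
  const int rows = k * k * k * cin;
  const int plane = n1 * n2;
  const R_xlen_t vox = static_cast<R_xlen_t>(plane) * n3;
  arma::mat dW(rows, cout, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  const int zs0 = slab_size(rows, plane, n3);
  arma::mat col(static_cast<size_t>(plane) * zs0, rows);
  arma::mat doutS(static_cast<size_t>(plane) * zs0, cout);
  for (int z0 = 0; z0 < n3; z0 += zs0) {
    const int zs = std::min(zs0, n3 - z0);
    const int ncols = plane * zs;
    arma::mat colv(col.memptr(), ncols, rows, false, true);
    im2col_slab(x.begin(), colv, n1, n2, n3, cin, k, pad, z0, zs);
    arma::mat doutv(doutS.memptr(), ncols, cout, false, true);
    for (int o = 0; o < cout; ++o) {
      const double *src = dout.begin() + static_cast<R_xlen_t>(o) * vox + static_cast<R_xlen_t>(z0) * plane;
      double *dst = doutv.colptr(o);
      double acc = 0.0;
      for (int t = 0; t < ncols; ++t) { dst[t] = src[t]; acc += src[t]; }
      db[o] += acc;
    }
    dW += colv.t() * doutv;
  }
  // flipped, transposed kernel: wT[di,dj,dk,o,c] = w[k-1-di, k-1-dj, k-1-dk, c, o]
  arma::vec wT(rows * cout);
  for (int c = 0; c < cin; ++c)
    for (int o = 0; o < cout; ++o)
      for (int dk = 0; dk < k; ++dk)
        for (int dj = 0; dj < k; ++dj)
          for (int di = 0; di < k; ++di) {
            const int src = di + k * (dj + k * (dk + k * (c + cin * (R_xlen_t)o)));
            const int dst = (k - 1 - di) + k * ((k - 1 - dj) + k * ((k - 1 - dk) + k * (o + cout * (R_xlen_t)c)));
            wT[dst] = w[src];
          }
  NumericVector dx(vox * cin);
  conv_core_fwd(dout.begin(), wT.memptr(), nullptr, dx.begin(),
                n1, n2, n3, cout, k, cin);
  dx.attr("dim") = IntegerVector::create(n1, n2, n3, cin);
  NumericVector dwv(static_cast<R_xlen_t>(rows) * cout);
  for (int t = 0; t < rows * cout; ++t) dwv[t] = dW[t];
  dwv.attr("dim") = w.attr("dim");
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = wrap(db));
}

// 2x max pooling per channel; spatial dims must be even.
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], C = xdim[3];
  const int m1 = n1 / 2, m2 = n2 / 2, m3 = n3 / 2;
  NumericVector out(static_cast<R_xlen_t>(m1) * m2 * m3 * C);
  IntegerVector arg(out.size());
  R_xlen_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < m3; ++z)
      for (int j = 0; j < m2; ++j)
        for (int i = 0; i < m1; ++i, ++p) {
          double best = -INFINITY; int bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                int q = idx4(2 * i + di, 2 * j + dj, 2 * z + dz, c, n1, n2, n3);
                if (x[q] > best) { best = x[q]; bidx = q; }
              }
          out[p] = best; arg[p] = bidx;
        }
  out.attr("dim") = IntegerVector::create(m1, m2, m3, C);
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector dout, IntegerVector argmax,
                                IntegerVector xdim) {
  NumericVector dx(static_cast<R_xlen_t>(xdim[0]) * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t p = 0; p < dout.size(); ++p) dx[argmax[p]] += dout[p];
  dx.attr("dim") = xdim;
  return dx;
}

// nearest-neighbour 2x upsampling per channel
// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, IntegerVector xdim) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2], C = xdim[3];
  const int m1 = 2 * n1, m2 = 2 * n2, m3 = 2 * n3;
  NumericVector out(static_cast<R_xlen_t>(m1) * m2 * m3 * C);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < m3; ++z)
      for (int j = 0; j < m2; ++j) {
        const double *src = x.begin() + idx4(0, j / 2, z / 2, c, n1, n2, n3);
        double *dst = out.begin() + idx4(0, j, z, c, m1, m2, m3);
        for (int i = 0; i < m1; ++i) dst[i] = src[i / 2];
      }
  out.attr("dim") = IntegerVector::create(m1, m2, m3, C);
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector dout, IntegerVector odim) {
  const int m1 = odim[0], m2 = odim[1], m3 = odim[2], C = odim[3];
  const int n1 = m1 / 2, n2 = m2 / 2, n3 = m3 / 2;
  NumericVector dx(static_cast<R_xlen_t>(n1) * n2 * n3 * C);
  for (int c = 0; c < C; ++c)
    for (int z = 0; z < m3; ++z)
      for (int j = 0; j < m2; ++j) {
        const double *src = dout.begin() + idx4(0, j, z, c, m1, m2, m3);
        double *dst = dx.begin() + idx4(0, j / 2, z / 2, c, n1, n2, n3);
        for (int i = 0; i < m1; ++i) dst[i / 2] += src[i];
      }
  dx.attr("dim") = IntegerVector::create(n1, n2, n3, C);
  return dx;
}

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Resize a single-channel 3D grid to odim. Voxel centers map by
// in = (out + 0.5) * n_in / n_out - 0.5, clamped to the grid, so constants
// are preserved and a same-size resize is the identity.
// [[Rcpp::export]]
NumericVector resize3d_cpp(NumericVector x, IntegerVector xdim,
                           IntegerVector odim, bool nearest) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2];
  const int m1 = odim[0], m2 = odim[1], m3 = odim[2];
  NumericVector out(static_cast<R_xlen_t>(m1) * m2 * m3);
  const double s1 = (double)n1 / m1, s2 = (double)n2 / m2, s3 = (double)n3 / m3;
  R_xlen_t p = 0;
  for (int z = 0; z < m3; ++z) {
    const double cz = clampd((z + 0.5) * s3 - 0.5, 0.0, n3 - 1.0);
    for (int j = 0; j < m2; ++j) {
      const double cj = clampd((j + 0.5) * s2 - 0.5, 0.0, n2 - 1.0);
      for (int i = 0; i < m1; ++i, ++p) {
        const double ci = clampd((i + 0.5) * s1 - 0.5, 0.0, n1 - 1.0);
        if (nearest) {
          int ii = (int)std::lround(ci), jj = (int)std::lround(cj), zz = (int)std::lround(cz);
          out[p] = x[idx4(ii, jj, zz, 0, n1, n2, n3)];
        } else {
          int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj), z0 = (int)std::floor(cz);
          int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1), z1 = std::min(z0 + 1, n3 - 1);
          double fi = ci - i0, fj = cj - j0, fz = cz - z0;
          double v = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                double wgt = (di ? fi : 1 - fi) * (dj ? fj : 1 - fj) * (dz ? fz : 1 - fz);
                if (wgt == 0.0) continue;
                v += wgt * x[idx4(di ? i1 : i0, dj ? j1 : j0, dz ? z1 : z0, 0, n1, n2, n3)];
              }
          out[p] = v;
        }
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// Resample a single-channel grid under the affine map: for each output voxel p
// (0-based), the source coordinate is A %*% (p - c) + c + t with c the grid
// center; voxels mapping outside the grid take `fill`.
// [[Rcpp::export]]
NumericVector affine3d_cpp(NumericVector x, IntegerVector xdim,
                           NumericMatrix A, NumericVector t,
                           bool nearest, double fill) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2];
  NumericVector out(x.size());
  const double c1 = (n1 - 1) / 2.0, c2 = (n2 - 1) / 2.0, c3 = (n3 - 1) / 2.0;
  R_xlen_t p = 0;
  for (int z = 0; z < n3; ++z)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++p) {
        const double u1 = i - c1, u2 = j - c2, u3 = z - c3;
        const double ci = A(0,0)*u1 + A(0,1)*u2 + A(0,2)*u3 + c1 + t[0];
        const double cj = A(1,0)*u1 + A(1,1)*u2 + A(1,2)*u3 + c2 + t[1];
        const double cz = A(2,0)*u1 + A(2,1)*u2 + A(2,2)*u3 + c3 + t[2];
        if (nearest) {
          int ii = (int)std::lround(ci), jj = (int)std::lround(cj), zz = (int)std::lround(cz);
          out[p] = (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || zz < 0 || zz >= n3)
                     ? fill : x[idx4(ii, jj, zz, 0, n1, n2, n3)];
        } else {
          if (ci < 0 || ci > n1 - 1 || cj < 0 || cj > n2 - 1 || cz < 0 || cz > n3 - 1) {
            out[p] = fill; continue;
          }
          int i0 = (int)std::floor(ci), j0 = (int)std::floor(cj), z0 = (int)std::floor(cz);
          int i1 = std::min(i0 + 1, n1 - 1), j1 = std::min(j0 + 1, n2 - 1), z1 = std::min(z0 + 1, n3 - 1);
          double fi = ci - i0, fj = cj - j0, fz = cz - z0;
          double v = 0.0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dj2 = 0; dj2 < 2; ++dj2)
              for (int di = 0; di < 2; ++di) {
                double wgt = (di ? fi : 1 - fi) * (dj2 ? fj : 1 - fj) * (dz ? fz : 1 - fz);
                if (wgt == 0.0) continue;
                v += wgt * x[idx4(di ? i1 : i0, dj2 ? j1 : j0, dz ? z1 : z0, 0, n1, n2, n3)];
              }
          out[p] = v;
        }
      }
  out.attr("dim") = xdim;
  return out;
}

// separable Gaussian smoothing with reflected boundaries (sigma in voxels)
// [[Rcpp::export]]
NumericVector gauss3d_cpp(NumericVector x, IntegerVector xdim, double sigma) {
  const int n1 = xdim[0], n2 = xdim[1], n3 = xdim[2];
  if (sigma <= 0) return clone(x);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int t = -rad; t <= rad; ++t) { ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma)); s += ker[t + rad]; }
  for (auto &v : ker) v /= s;
  NumericVector a = clone(x), b(x.size());
  const int dims[3] = {n1, n2, n3};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = dims[ax];
    R_xlen_t p = 0;
    for (int z = 0; z < n3; ++z)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i, ++p) {
          const int pos = ax == 0 ? i : (ax == 1 ? j : z);
          double v = 0;
          for (int t = -rad; t <= rad; ++t) {
            int q = pos + t;
            if (q < 0) q = -q - 1;
            if (q >= n) q = 2 * n - q - 1;
            q = std::max(0, std::min(n - 1, q));
            int qi = ax == 0 ? q : i, qj = ax == 1 ? q : j, qz = ax == 2 ? q : z;
            v += ker[t + rad] * a[idx4(qi, qj, qz, 0, n1, n2, n3)];
          }
          b[p] = v;
        }
    std::swap(a, b);
  }
  a.attr("dim") = xdim;
  return a;
}
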