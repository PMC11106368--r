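// 3x3x3 zero-padded ("same") 3D convolution via im2col + BLAS GEMM,
// with the exact adjoint for backpropagation, plus 2x2x2 max pooling.
// These are the compute kernels behind the patch-based 3D U-Net.
// Arithmetic runs in single precision: the kernels are memory-bound and
// the training gradients are far above float round-off.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static int slab_len(int nx, int ny, int R, int nz) {
  double cap = 8e6;  // ~32 MB of floats for the im2col buffer
  int z = (int)std::floor(cap / ((double)nx * ny * R));
  if (z < 1) z = 1;
  if (z > nz) z = nz;
  return z;
}

// Fill Mt (n x R, n = nx*ny*zlen voxels of slab [z0, z0+zlen)) with the
// 27-neighbourhood of every voxel, channel-major rows:
// row = ((c*3 + kz+1)*3 + ky+1)*3 + kx+1.
static void im2col_slab(const double *x, int nx, int ny, int nz, int cin,
                        int z0, int zlen, arma::fmat &Mt) {
  Mt.zeros();
  for (int c = 0; c < cin; ++c) {
    const double *xc = x + (R_xlen_t)nx * ny * nz * c;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int row = ((c * 3 + (kz + 1)) * 3 + (ky + 1)) * 3 + (kx + 1);
          float *mcol = Mt.colptr(row);
          for (int k = z0; k < z0 + zlen; ++k) {
            const int kk = k + kz;
            if (kk < 0 || kk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int jj = j + ky;
              if (jj < 0 || jj >= ny) continue;
              const int i0 = std::max(0, -kx), i1 = std::min(nx, nx - kx);
              if (i1 <= i0) continue;
              const double *src =
                  xc + (i0 + kx) + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
              float *dst = mcol + i0 + (arma::uword)nx *
                                           (j + (arma::uword)ny * (k - z0));
              for (int t = 0; t < i1 - i0; ++t) dst[t] = (float)src[t];
            }
          }
        }
  }
}

static arma::fmat to_f(const NumericMatrix &W) {
  arma::fmat Wf(W.nrow(), W.ncol());
  std::copy(W.begin(), W.end(), Wf.begin());
  return Wf;
}

// [[Rcpp::export]]
NumericVector c_conv3d_fwd(NumericVector x, IntegerVector dims,
                           NumericMatrix W, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int R = 27 * cin, cout = W.ncol();
  NumericVector out((R_xlen_t)nx * ny * nz * cout);
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  arma::fmat Wf = to_f(W);
  const int zl = slab_len(nx, ny, R, nz);
  arma::fmat Mt((arma::uword)nx * ny * zl, R);
  for (int z0 = 0; z0 < nz; z0 += zl) {
    const int zlen = std::min(zl, nz - z0);
    arma::fmat Mts;
    arma::fmat *M = &Mt;
    if (zlen != zl) {
      Mts.set_size((arma::uword)nx * ny * zlen, R);
      M = &Mts;
    }
    im2col_slab(x.begin(), nx, ny, nz, cin, z0, zlen, *M);
    arma::fmat Yt = (*M) * Wf;  // n x cout
    for (int co = 0; co < cout; ++co) {
      double *dst = out.begin() + (R_xlen_t)nx * ny * (z0 + (R_xlen_t)nz * co);
      const float *src = Yt.colptr(co);
      const R_xlen_t n = (R_xlen_t)nx * ny * zlen;
      const double bc = b[co];
      for (R_xlen_t t = 0; t < n; ++t) dst[t] = (double)src[t] + bc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List c_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                  NumericVector dy) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int R = 27 * cin, cout = W.ncol();
  arma::fmat Wf = to_f(W);
  NumericVector dx((R_xlen_t)nx * ny * nz * cin);
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  arma::fmat dW(R, cout, arma::fill::zeros);
  arma::fvec db(cout, arma::fill::zeros);
  const int zl = slab_len(nx, ny, R, nz);
  arma::fmat Mt((arma::uword)nx * ny * zl, R);
  for (int z0 = 0; z0 < nz; z0 += zl) {
    const int zlen = std::min(zl, nz - z0);
    arma::fmat Mts;
    arma::fmat *M = &Mt;
    if (zlen != zl) {
      Mts.set_size((arma::uword)nx * ny * zlen, R);
      M = &Mts;
    }
    im2col_slab(x.begin(), nx, ny, nz, cin, z0, zlen, *M);
    const arma::uword n = (arma::uword)nx * ny * zlen;
    arma::fmat dYt(n, cout);
    for (int co = 0; co < cout; ++co) {
      const double *src =
          dy.begin() + (R_xlen_t)nx * ny * (z0 + (R_xlen_t)nz * co);
      float *dst = dYt.colptr(co);
      for (arma::uword t = 0; t < n; ++t) dst[t] = (float)src[t];
    }
    dW += M->t() * dYt;
    db += arma::sum(dYt, 0).t();
    arma::fmat Gt = dYt * Wf.t();  // n x R
    // col2im: scatter-add each feature column back to input positions
    for (int c = 0; c < cin; ++c) {
      double *dxc = dx.begin() + (R_xlen_t)nx * ny * nz * c;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int row = ((c * 3 + (kz + 1)) * 3 + (ky + 1)) * 3 + (kx + 1);
            const float *g = Gt.colptr(row);
            for (int k = z0; k < z0 + zlen; ++k) {
              const int kk = k + kz;
              if (kk < 0 || kk >= nz) continue;
              for (int j = 0; j < ny; ++j) {
                const int jj = j + ky;
                if (jj < 0 || jj >= ny) continue;
                const int i0 = std::max(0, -kx), i1 = std::min(nx, nx - kx);
                if (i1 <= i0) continue;
                double *dst =
                    dxc + (i0 + kx) + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
                const float *src = g + i0 + (arma::uword)nx *
                                           (j + (arma::uword)ny * (k - z0));
                for (int t = 0; t < i1 - i0; ++t) dst[t] += (double)src[t];
              }
            }
          }
    }
  }
  arma::mat dWd = arma::conv_to<arma::mat>::from(dW);
  arma::vec dbd = arma::conv_to<arma::vec>::from(db);
  return List::create(_["dx"] = dx, _["dW"] = wrap(dWd), _["db"] = wrap(dbd));
}

// [[Rcpp::export]]
List c_maxpool_fwd(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], C = dims[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  NumericVector y((R_xlen_t)ox * oy * oz * C);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  idx.attr("dim") = IntegerVector::create(ox, oy, oz, C);
  const double *xd = x.begin();
  R_xlen_t t = 0;
  for (int c = 0; c < C; ++c) {
    const R_xlen_t off = (R_xlen_t)nx * ny * nz * c;
    for (int k = 0; k < oz; ++k)
      for (int j = 0; j < oy; ++j)
        for (int i = 0; i < ox; ++i, ++t) {
          double best = -HUGE_VAL;
          R_xlen_t barg = 0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const R_xlen_t s =
                    off + (2 * i + di) +
                    (R_xlen_t)nx * ((2 * j + dj) + (R_xlen_t)ny * (2 * k + dk));
                if (xd[s] > best) { best = xd[s]; barg = s; }
              }
          y[t] = best;
          idx[t] = (int)barg;
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector c_maxpool_bwd(NumericVector dy, IntegerVector idx,
                            IntegerVector dimsX) {
  NumericVector dx((R_xlen_t)dimsX[0] * dimsX[1] * dimsX[2] * dimsX[3]);
  dx.attr("dim") = dimsX;
  for (R_xlen_t t = 0; t < dy.size(); ++t) dx[idx[t]] += dy[t];
  return dx;
}
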