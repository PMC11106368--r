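#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3D array at arbitrary voxel coordinates
// (0-based, continuous). Points outside the grid contribute zero,
// matching the zero-background convention of brain-extracted images.
// [[Rcpp::export]]
NumericVector c_trilinear_sample(NumericVector data, IntegerVector dims,
                                 NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
              k0 = (int)std::floor(z);
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
      const int k = k0 + dz;
      if (k < 0 || k >= nz) continue;
      const double wz = dz ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int dy = 0; dy < 2; ++dy) {
        const int j = j0 + dy;
        if (j < 0 || j >= ny) continue;
        const double wy = dy ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int dx = 0; dx < 2; ++dx) {
          const int i = i0 + dx;
          if (i < 0 || i >= nx) continue;
          const double wx = dx ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          acc += wx * wy * wz *
                 d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// Nearest-neighbour sampling; preserves the value set of the input.
// [[Rcpp::export]]
NumericVector c_nearest_sample(NumericVector data, IntegerVector dims,
                               NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *d = data.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    const int i = (int)std::lround(pts(p, 0));
    const int j = (int)std::lround(pts(p, 1));
    const int k = (int)std::lround(pts(p, 2));
    out[p] = (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
                 ? 0.0
                 : d[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  }
  return out;
}

static void gauss_axis(std::vector<double> &src, std::vector<double> &dst,
                       int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) { dst = src; return; }
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * rad + 1);
  for (int t = -rad; t <= rad; ++t)
    ker[t + rad] = std::exp(-0.5 * t * t / (sigma * sigma));
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int na = n[axis];
  const R_xlen_t sa = stride[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idxa = axis == 0 ? i : (axis == 1 ? j : k);
        const R_xlen_t base = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        double acc = 0.0, wsum = 0.0;
        const int lo = std::max(-idxa, -rad), hi = std::min(na - 1 - idxa, rad);
        for (int t = lo; t <= hi; ++t) {
          const double w = ker[t + rad];
          acc += w * src[base + t * sa];
          wsum += w;
        }
        dst[base] = acc / wsum;  // kernel renormalised at the borders
      }
}

// Separable Gaussian smoothing with per-axis sigma in voxels.
// [[Rcpp::export]]
NumericVector c_gauss_smooth(NumericVector data, IntegerVector dims,
                             NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(data.begin(), data.end()), b(a.size());
  gauss_axis(a, b, nx, ny, nz, 0, sigma[0]);
  gauss_axis(b, a, nx, ny, nz, 1, sigma[1]);
  gauss_axis(a, b, nx, ny, nz, 2, sigma[2]);
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = dims;
  return out;
}
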