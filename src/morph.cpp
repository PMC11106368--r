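#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Ball erosion: a voxel survives iff every offset in the (physical-radius)
// ball lands on a foreground voxel; offsets falling outside the grid count
// as background, so the mask is eroded at the image border too.
// [[Rcpp::export]]
IntegerVector c_erode(IntegerVector mask, IntegerVector dims,
                      IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = offsets.nrow();
  IntegerVector out(mask.size());
  out.attr("dim") = dims;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) { out[idx] = 0; continue; }
        int keep = 1;
        for (int o = 0; o < K; ++o) {
          const int ii = i + offsets(o, 0), jj = j + offsets(o, 1),
                    kk = k + offsets(o, 2);
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz ||
              !mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
            keep = 0;
            break;
          }
        }
        out[idx] = keep;
      }
  return out;
}

// 26-connected component labelling by BFS in raster-scan order, so the
// component containing the smallest linear voxel index gets label 1, the
// next new component label 2, and so on (deterministic tie-breaking).
// [[Rcpp::export]]
List c_label26(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  lab.attr("dim") = dims;
  std::vector<int> sizes;
  std::queue<R_xlen_t> q;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    int sz = 0;
    lab[s] = next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t cur = q.front();
      q.pop();
      ++sz;
      const int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            const int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            const R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[nb] && !lab[nb]) {
              lab[nb] = next;
              q.push(nb);
            }
          }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = lab, _["sizes"] = wrap(sizes));
}
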