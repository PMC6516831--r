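#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 26-connected (or 6-connected) labelling of a 3D logical array.
// `mask` is a LogicalVector with dim attribute (nz, ny, nx), column-major.
// Returns an IntegerVector of the same shape; labels are in scan order
// (first-encountered component gets label 1) — callers relabel by size.
// [[Rcpp::export(name = ".label_components_3d")]]
IntegerVector label_components_3d(LogicalVector mask, int connectivity = 26) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3D array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;

  // neighbour offsets in (dz, dy, dx)
  std::vector<int> dz, dy, dx;
  for (int ddx = -1; ddx <= 1; ++ddx)
    for (int ddy = -1; ddy <= 1; ++ddy)
      for (int ddz = -1; ddz <= 1; ++ddz) {
        if (ddx == 0 && ddy == 0 && ddz == 0) continue;
        int manh = std::abs(ddx) + std::abs(ddy) + std::abs(ddz);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(ddz); dy.push_back(ddy); dx.push_back(ddx);
      }
  const int nnb = (int)dz.size();

  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t idx = q.front(); q.pop();
      int z = (int)(idx % nz);
      int y = (int)((idx / nz) % ny);
      int x = (int)(idx / ((R_xlen_t)nz * ny));
      for (int k = 0; k < nnb; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t nidx = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[nidx] && labels[nidx] == 0) {
          labels[nidx] = next_label;
          q.push(nidx);
        }
      }
    }
  }
  return labels;
}

// Strict 26-neighbourhood local maxima of a 3D numeric array above `floor`.
// Returns linear 1-based indices of voxels strictly greater than every
// in-bounds neighbour.
// [[Rcpp::export(name = ".local_maxima_3d")]]
IntegerVector local_maxima_3d(NumericVector img, double floor_value) {
  IntegerVector dims = img.attr("dim");
  if (dims.size() != 3) stop("img must be a 3D array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> out;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        double v = img[idx];
        if (!(v > floor_value)) continue;
        bool is_max = true;
        for (int ddx = -1; ddx <= 1 && is_max; ++ddx)
          for (int ddy = -1; ddy <= 1 && is_max; ++ddy)
            for (int ddz = -1; ddz <= 1 && is_max; ++ddz) {
              if (ddx == 0 && ddy == 0 && ddz == 0) continue;
              int zz = z + ddz, yy = y + ddy, xx = x + ddx;
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                  xx < 0 || xx >= nx) continue;
              R_xlen_t nidx =
                (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (img[nidx] >= v) is_max = false;
            }
        if (is_max) out.push_back((int)idx + 1);
      }
  return wrap(out);
}
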