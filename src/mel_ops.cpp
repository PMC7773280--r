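#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Volumes are stored (z, y, x) column-major, so the linear index of voxel
// (z, y, x) (0-based) is z + nz * (y + ny * x) and z varies fastest.
// Raster-scan order therefore means increasing linear index.

// 26-connected component labelling of a 3D logical mask. Labels are
// assigned in raster-scan order of each component's first voxel, which
// makes the labelling deterministic for a given mask.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int z = (int)(c % nz);
      R_xlen_t r = c / nz;
      int y = (int)(r % ny);
      int x = (int)(r / ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (j == c) continue;
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Hysteresis support: voxels strictly above `high` seed a flood fill that
// may extend through any voxel with intensity >= `low` (26-connectivity).
// [[Rcpp::export(name = ".hysteresis_mask_3d")]]
LogicalVector hysteresis_mask_3d(NumericVector img, IntegerVector dims,
                                 double low, double high) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("img length does not match dims");
  LogicalVector keep(n);
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (img[i] > high && !keep[i]) {
      keep[i] = true;
      stack.push_back(i);
    }
  }
  while (!stack.empty()) {
    R_xlen_t c = stack.back();
    stack.pop_back();
    int z = (int)(c % nz);
    R_xlen_t r = c / nz;
    int y = (int)(r % ny);
    int x = (int)(r / ny);
    for (int dx = -1; dx <= 1; ++dx) {
      int xx = x + dx;
      if (xx < 0 || xx >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (j == c || keep[j]) continue;
          if (img[j] >= low) {
            keep[j] = true;
            stack.push_back(j);
          }
        }
      }
    }
  }
  keep.attr("dim") = dims;
  return keep;
}

// Closest pair of voxels between two voxel sets under anisotropic physical
// spacing. `a`, `b` are m x 3 / n x 3 integer matrices of (z, y, x) voxel
// indices; `spacing` is (dz, dy, dx) in micrometres. Ties on the squared
// distance are broken by the lexicographically smallest (az,ay,ax,bz,by,bx).
// [[Rcpp::export(name = ".min_edge_distance")]]
List min_edge_distance(IntegerMatrix a, IntegerMatrix b, NumericVector spacing) {
  if (a.nrow() == 0 || b.nrow() == 0) stop("empty edge set");
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  double best = R_PosInf;
  int bi = 0, bj = 0;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dz = (a(i, 0) - b(j, 0)) * sz;
      double dy = (a(i, 1) - b(j, 1)) * sy;
      double dx = (a(i, 2) - b(j, 2)) * sx;
      double d2 = dz * dz + dy * dy + dx * dx;
      if (d2 > best) continue;
      bool take = d2 < best;
      if (!take) {
        // tie: lexicographic comparison of the concatenated voxel pair
        int cur[6] = {a(i, 0), a(i, 1), a(i, 2), b(j, 0), b(j, 1), b(j, 2)};
        int old[6] = {a(bi, 0), a(bi, 1), a(bi, 2), b(bj, 0), b(bj, 1), b(bj, 2)};
        for (int k = 0; k < 6; ++k) {
          if (cur[k] != old[k]) {
            take = cur[k] < old[k];
            break;
          }
        }
      }
      if (take) {
        best = d2;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(
      _["d_um"] = std::sqrt(best),
      _["a"] = IntegerVector::create(a(bi, 0), a(bi, 1), a(bi, 2)),
      _["b"] = IntegerVector::create(b(bj, 0), b(bj, 1), b(bj, 2)));
}
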