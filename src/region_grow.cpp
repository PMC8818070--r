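#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

// Seeded threshold-connected flood fill on a 3D scalar volume.
// Seeds are 1-based (x, y, z) voxel coordinates; a voxel joins the region
// when value >= threshold, it lies inside `brain`, and it is connected to a
// seed under the requested neighbourhood (6 = faces, 26 = faces+edges+corners).
// [[Rcpp::export(name = ".flood_fill3d")]]
LogicalVector flood_fill3d(NumericVector map, IntegerVector dim,
                           IntegerMatrix seeds, double threshold,
                           LogicalVector brain, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (map.size() != n || brain.size() != n)
    stop("map/brain size does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  std::vector<char> visited(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (int s = 0; s < seeds.nrow(); ++s) {
    int x = seeds(s, 0) - 1, y = seeds(s, 1) - 1, z = seeds(s, 2) - 1;
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz)
      stop("seed outside image bounds");
    R_xlen_t idx = x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
    if (!brain[idx]) stop("seed outside brain mask");
    if (map[idx] < threshold) stop("seed below threshold");
    if (!visited[idx]) { visited[idx] = 1; stack.push_back(idx); }
  }

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  LogicalVector out(n, false);
  while (!stack.empty()) {
    R_xlen_t idx = stack.back();
    stack.pop_back();
    out[idx] = true;
    int z = (int)(idx / ((R_xlen_t)nx * ny));
    R_xlen_t rem = idx - (R_xlen_t)z * nx * ny;
    int y = (int)(rem / nx), x = (int)(rem % nx);
    for (const auto &o : offs) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t j = xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
      if (visited[j]) continue;
      visited[j] = 1;
      if (!brain[j] || map[j] < threshold) continue;
      stack.push_back(j);
    }
  }
  return out;
}
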