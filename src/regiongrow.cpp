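#include <Rcpp.h>
#include <vector>
#include <array>
#include <queue>
using namespace Rcpp;

// Seeded region growing: breadth-first front evolution restricted to
// voxels with CT value strictly greater than `r`. `seeds` holds 0-based
// voxel index triples. Connectivity 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".region_grow")]]
LogicalVector region_grow(NumericVector values, IntegerVector dims,
                          IntegerMatrix seeds, double r, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nb = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nb == 0) continue;
        if (connectivity == 6 && nb != 1) continue;
        offs.push_back({dx, dy, dz});
      }

  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    R_xlen_t lin = seeds(s, 0) + (R_xlen_t)nx * (seeds(s, 1) + (R_xlen_t)ny * seeds(s, 2));
    if (!out[lin]) { out[lin] = true; q.push(lin); }
  }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int i = cur % nx, j = (cur / nx) % ny, k = cur / ((R_xlen_t)nx * ny);
    for (const auto& o : offs) {
      int x = i + o[0], y = j + o[1], z = k + o[2];
      if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
      R_xlen_t lin = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      if (!out[lin] && values[lin] > r) { out[lin] = true; q.push(lin); }
    }
  }
  return out;
}
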