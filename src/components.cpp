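#include <Rcpp.h>
#include <array>
#include <cstdlib>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling by breadth-first search.
// binary: logical volume flattened x-fastest; dim: c(nx, ny, nz);
// connectivity: 6, 18 or 26. Labels are assigned in scan order (x fastest);
// callers re-order by size afterwards. 0 = background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector binary, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (binary.size() != nvox) stop("binary does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }

  IntegerVector labels(nvox, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!binary[s] || labels[s] != 0) continue;
    ++next;
    labels[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t v = queue[head++];
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (auto& o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
        if (binary[w] && labels[w] == 0) {
          labels[w] = next;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}
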