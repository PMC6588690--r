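#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Average (mid) ranks of x, ties -> mean rank. Matches base::rank(ties = "average").
static void avg_rank(const double* x, int n, double* out) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0; // mean of ranks i+1..j+1
    for (int k = i; k <= j; ++k) out[idx[k]] = r;
    i = j + 1;
  }
}

// Voxel-wise Kendall's W over the 3x3x3 neighbourhood restricted to the mask.
// data: nvox x nt matrix (in-mask rows hold the series, flattened x-fastest),
// dim: volume dims, mask: logical volume (same flattening),
// min_neighbors: neighbourhood count (incl. centre) required for a defined value.
// Returns nvox vector, NA_real_ where undefined or out of mask.
// [[Rcpp::export(name = ".reho_map_cpp")]]
NumericVector reho_map_cpp(NumericMatrix data, IntegerVector dim,
                           LogicalVector mask, int min_neighbors) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int nt = data.ncol();
  if (data.nrow() != nvox || mask.size() != nvox)
    stop("data/mask do not match the volume dimensions");

  // rank every in-mask series once
  NumericMatrix ranks(nvox, nt);
  std::vector<double> buf(nt), rbuf(nt);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (!mask[v]) continue;
    for (int t = 0; t < nt; ++t) buf[t] = data(v, t);
    avg_rank(buf.data(), nt, rbuf.data());
    for (int t = 0; t < nt; ++t) ranks(v, t) = rbuf[t];
  }

  NumericVector out(nvox, NA_REAL);
  const double N = nt;
  std::vector<double> Ri(nt);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
        if (!mask[v]) continue;
        std::fill(Ri.begin(), Ri.end(), 0.0);
        int K = 0;
        for (int dz = -1; dz <= 1; ++dz) {
          int zz = z + dz;
          if (zz < 0 || zz >= nz) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              R_xlen_t w = (R_xlen_t)xx + nx * ((R_xlen_t)yy + (R_xlen_t)ny * zz);
              if (!mask[w]) continue;
              ++K;
              for (int t = 0; t < nt; ++t) Ri[t] += ranks(w, t);
            }
          }
        }
        if (K < min_neighbors || K < 2) continue;
        double S = 0.0, Rbar = 0.0;
        for (int t = 0; t < nt; ++t) { S += Ri[t] * Ri[t]; Rbar += Ri[t]; }
        Rbar /= N;
        double denom = (double)K * K * (N * N * N - N) / 12.0;
        out[v] = (S - N * Rbar * Rbar) / denom;
      }
  return out;
}
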