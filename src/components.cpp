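// 3D connected-component labeling of a binary mask by breadth-first search.
// Connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  SEXP ds = mask.attr("dim");
  if (Rf_isNull(ds)) stop("mask must be a 3-d array");
  IntegerVector dim(ds);
  if (dim.size() != 3) stop("mask must be a 3-d array");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        off.push_back(dx);
        off.push_back(dy);
        off.push_back(dz);
      }

  const std::size_t nvox = (std::size_t)nx * ny * nz;
  IntegerVector lab(nvox);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<std::size_t> queue;
  for (std::size_t s = 0; s < nvox; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    while (!queue.empty()) {
      const std::size_t v = queue.back();
      queue.pop_back();
      const int x = (int)(v % nx);
      const int y = (int)((v / nx) % ny);
      const int z = (int)(v / ((std::size_t)nx * ny));
      for (std::size_t k = 0; k < off.size(); k += 3) {
        const int xx = x + off[k], yy = y + off[k + 1], zz = z + off[k + 2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        const std::size_t u = xx + (std::size_t)nx * (yy + (std::size_t)ny * zz);
        if (mask[u] != 0 && lab[u] == 0) {
          lab[u] = next;
          queue.push_back(u);
        }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}
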