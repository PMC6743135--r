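#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected components of a logical 3D grid.
// Returns integer labels (0 = background), component count and sizes,
// ordered so that component 1 is the largest.
// [[Rcpp::export]]
List cc_label3d(LogicalVector grid, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (grid.size() != n) stop("grid length does not match dim");
  IntegerVector labels(n, 0);
  std::vector<int> sizes;
  std::vector<R_xlen_t> stack;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  int ncomp = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!grid[seed] || labels[seed] != 0) continue;
    ++ncomp;
    int size = 0;
    stack.clear();
    stack.push_back(seed);
    labels[seed] = ncomp;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      ++size;
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / sz);
      if (i > 0      && grid[v - sx] && !labels[v - sx]) { labels[v - sx] = ncomp; stack.push_back(v - sx); }
      if (i < nx - 1 && grid[v + sx] && !labels[v + sx]) { labels[v + sx] = ncomp; stack.push_back(v + sx); }
      if (j > 0      && grid[v - sy] && !labels[v - sy]) { labels[v - sy] = ncomp; stack.push_back(v - sy); }
      if (j < ny - 1 && grid[v + sy] && !labels[v + sy]) { labels[v + sy] = ncomp; stack.push_back(v + sy); }
      if (k > 0      && grid[v - sz] && !labels[v - sz]) { labels[v - sz] = ncomp; stack.push_back(v - sz); }
      if (k < nz - 1 && grid[v + sz] && !labels[v + sz]) { labels[v + sz] = ncomp; stack.push_back(v + sz); }
    }
    sizes.push_back(size);
  }
  // relabel so the largest component is 1
  IntegerVector order(ncomp);
  std::vector<int> idx(ncomp);
  for (int c = 0; c < ncomp; ++c) idx[c] = c;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> rank(ncomp);
  IntegerVector sorted_sizes(ncomp);
  for (int r = 0; r < ncomp; ++r) {
    rank[idx[r]] = r + 1;
    sorted_sizes[r] = sizes[idx[r]];
  }
  for (R_xlen_t v = 0; v < n; ++v)
    if (labels[v] != 0) labels[v] = rank[labels[v] - 1];
  return List::create(_["labels"] = labels,
                      _["n_components"] = ncomp,
                      _["sizes"] = sorted_sizes);
}
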