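#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' 8-connected component labeling of a binary mask
//'
//' Two-pass union-find labeling; labels are consecutive integers starting
//' at 1 in raster (column-major) order of first occurrence.
//'
//' @param mask logical matrix
//' @return integer matrix of component labels (0 = background)
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  // first pass, column-major: neighbors already visited are
  // (r-1, c-1), (r-1, c), (r+1, c-1), (r, c-1)... in column-major order the
  // visited neighbors of (r, c) are (r-1, c) and column c-1 rows r-1..r+1
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) continue;
      int lbl = 0;
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (auto &p : nb) {
        if (p[0] < 0 || p[0] >= H || p[1] < 0) continue;
        int l2 = lab(p[0], p[1]);
        if (l2 == 0) continue;
        if (lbl == 0) lbl = l2;
        else unite(lbl, l2);
      }
      if (lbl == 0) {
        lbl = (int)parent.size();
        parent.push_back(lbl);
      }
      lab(r, c) = lbl;
    }
  }
  // second pass: flatten and relabel consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find(l);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  return lab;
}
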