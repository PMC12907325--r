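// Connected-component labeling of a binary mask (two-pass union-find).
// Components are numbered 1..K in order of first appearance in a row-major
// (y-major) scan, so the component containing the lexicographically
// smallest (y, x) pixel has the smallest label.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int findRoot(std::vector<int>& par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> par(1, 0);       // par[0] unused
  // first pass: scan y-major (row by row), x within row
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x)) continue;
      int neigh[4]; int nn = 0;
      if (x > 0 && mask(y, x - 1)) neigh[nn++] = lab(y, x - 1);
      if (y > 0 && mask(y - 1, x)) neigh[nn++] = lab(y - 1, x);
      if (connectivity == 8) {
        if (y > 0 && x > 0 && mask(y - 1, x - 1)) neigh[nn++] = lab(y - 1, x - 1);
        if (y > 0 && x < W - 1 && mask(y - 1, x + 1)) neigh[nn++] = lab(y - 1, x + 1);
      }
      if (nn == 0) {
        int id = (int)par.size(); par.push_back(id); lab(y, x) = id;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) m = std::min(m, neigh[k]);
        lab(y, x) = m;
        for (int k = 0; k < nn; ++k) {
          int a = findRoot(par, m), b = findRoot(par, neigh[k]);
          if (a != b) par[std::max(a, b)] = std::min(a, b);
        }
      }
    }
  }
  // second pass: relabel roots compactly in scan order of first appearance
  std::vector<int> remap(par.size(), 0);
  int next = 0;
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      if (!lab(y, x)) continue;
      int r = findRoot(par, lab(y, x));
      if (!remap[r]) remap[r] = ++next;
      lab(y, x) = remap[r];
    }
  return lab;
}
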