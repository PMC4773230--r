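#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D binary morphology and connected-component labelling used by the lung
// segmentation. Arrays are column-major with dim = c(nslice, nrow, ncol);
// voxels outside the grid are treated as background.

static inline int lin(int i, int j, int k, int d0, int d1) {
  return i + d0 * (j + d1 * k);
}

// Label 26-connected components of a logical grid. Returns an integer grid
// with 0 for background and labels 1..n in first-encounter order.
// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector flags, IntegerVector dims) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const R_xlen_t n = flags.size();
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int k0 = 0; k0 < d2; ++k0)
    for (int j0 = 0; j0 < d1; ++j0)
      for (int i0 = 0; i0 < d0; ++i0) {
        int p = lin(i0, j0, k0, d0, d1);
        if (!flags[p] || lab[p]) continue;
        lab[p] = ++next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          int q = stack.back();
          stack.pop_back();
          int qi = q % d0, qj = (q / d0) % d1, qk = q / (d0 * d1);
          for (int dk = -1; dk <= 1; ++dk)
            for (int dj = -1; dj <= 1; ++dj)
              for (int di = -1; di <= 1; ++di) {
                if (!di && !dj && !dk) continue;
                int ni = qi + di, nj = qj + dj, nk = qk + dk;
                if (ni < 0 || ni >= d0 || nj < 0 || nj >= d1 ||
                    nk < 0 || nk >= d2)
                  continue;
                int np = lin(ni, nj, nk, d0, d1);
                if (flags[np] && !lab[np]) {
                  lab[np] = next;
                  stack.push_back(np);
                }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Erode (shrink) or dilate (grow) a logical grid by a structuring element
// given as an L x 3 matrix of integer voxel offsets.
// [[Rcpp::export(name = ".morph_binary")]]
LogicalVector morph_binary(LogicalVector flags, IntegerVector dims,
                           IntegerMatrix offsets, bool dilate) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const int L = offsets.nrow();
  LogicalVector out(flags.size(), false);
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        int p = lin(i, j, k, d0, d1);
        bool hit = dilate ? false : true;
        for (int l = 0; l < L; ++l) {
          int ni = i + offsets(l, 0), nj = j + offsets(l, 1),
              nk = k + offsets(l, 2);
          bool v = (ni >= 0 && ni < d0 && nj >= 0 && nj < d1 &&
                    nk >= 0 && nk < d2)
                       ? (bool)flags[lin(ni, nj, nk, d0, d1)]
                       : false;
          if (dilate && v)  { hit = true;  break; }
          if (!dilate && !v) { hit = false; break; }
        }
        out[p] = hit;
      }
  out.attr("dim") = dims;
  return out;
}
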