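#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected foreground components of a logical mask by iterative
// flood fill. Labels are assigned in column-major scan order starting at 1;
// background stays 0. connectivity is 4 (edge neighbors) or 8 (+diagonals).
// [[Rcpp::export(name = ".ccLabel")]]
IntegerMatrix ccLabel(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;

  const int di4[] = {-1, 1, 0, 0};
  const int dj4[] = {0, 0, -1, 1};
  const int di8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *di = (connectivity == 4) ? di4 : di8;
  const int *dj = (connectivity == 4) ? dj4 : dj8;
  const int nn = connectivity;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}
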