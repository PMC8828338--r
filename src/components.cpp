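#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdlib>
using namespace Rcpp;

// Connected-component labelling of a binary volume stored as an
// (slices, rows, cols) array. connectivity in {6, 18, 26}; per_slice = true
// restricts neighbourhoods to within-slice offsets (4- or 8-connectivity).
// [[Rcpp::export]]
IntegerVector label_components_cpp(const IntegerVector& mask,
                                   const int connectivity,
                                   const bool per_slice) {
  IntegerVector dm = mask.attr("dim");
  const int S = dm[0], R = dm[1], C = dm[2];
  const R_xlen_t n = (R_xlen_t)S * R * C;

  std::vector<std::array<int, 3> > offs;
  for (int ds = -1; ds <= 1; ++ds)
    for (int dr = -1; dr <= 1; ++dr)
      for (int dc = -1; dc <= 1; ++dc) {
        if (ds == 0 && dr == 0 && dc == 0) continue;
        const int a = std::abs(ds) + std::abs(dr) + std::abs(dc);
        if (connectivity == 6 && a > 1) continue;
        if (connectivity == 18 && a > 2) continue;
        if (per_slice && ds != 0) continue;
        offs.push_back({ds, dr, dc});
      }

  IntegerVector lab(n, 0);
  lab.attr("dim") = dm;
  std::vector<R_xlen_t> stack;
  int next = 0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int s = (int)(cur % S);
      const int r = (int)((cur / S) % R);
      const int c = (int)(cur / ((R_xlen_t)S * R));
      for (size_t o = 0; o < offs.size(); ++o) {
        const int s2 = s + offs[o][0], r2 = r + offs[o][1], c2 = c + offs[o][2];
        if (s2 < 0 || s2 >= S || r2 < 0 || r2 >= R || c2 < 0 || c2 >= C) continue;
        const R_xlen_t j = s2 + (R_xlen_t)S * (r2 + (R_xlen_t)R * c2);
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Per-slice binary median filter with an odd window and zero padding:
// output voxel = 1 iff the count of ones in the window is at least
// (window^2 + 1) / 2 (the median of window^2 binary values).
// [[Rcpp::export]]
IntegerVector median_filter_slices_cpp(const IntegerVector& mask, const int window) {
  IntegerVector dm = mask.attr("dim");
  const int S = dm[0], R = dm[1], C = dm[2];
  const int k = (window - 1) / 2;
  const int need = (window * window + 1) / 2;
  IntegerVector out((R_xlen_t)S * R * C);
  out.attr("dim") = dm;
  for (int s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      for (int r = 0; r < R; ++r) {
        int cnt = 0;
        for (int dc = -k; dc <= k; ++dc) {
          const int c2 = c + dc;
          if (c2 < 0 || c2 >= C) continue;
          for (int dr = -k; dr <= k; ++dr) {
            const int r2 = r + dr;
            if (r2 < 0 || r2 >= R) continue;
            cnt += mask[s + (R_xlen_t)S * (r2 + (R_xlen_t)R * c2)];
          }
        }
        out[s + (R_xlen_t)S * (r + (R_xlen_t)R * c)] = (cnt >= need) ? 1 : 0;
      }
    }
  }
  return out;
}
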