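#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Center-weighted median filter on a 2D field. The centre sample is
// replicated `center_weight` times in the median sample; borders use
// replicate padding. window must be odd.
// [[Rcpp::export(name = ".cwm_filter_cpp")]]
NumericMatrix cwm_filter_cpp(NumericMatrix x, int window, int center_weight) {
  if (window < 1 || window % 2 == 0)
    stop("window must be a positive odd integer");
  if (center_weight < 1 || center_weight % 2 == 0)
    stop("center_weight must be a positive odd integer");
  int nr = x.nrow(), nc = x.ncol(), h = window / 2;
  NumericMatrix out(nr, nc);
  int nsamp = window * window + center_weight - 1;
  std::vector<double> buf(nsamp);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf[k++] = x(ii, jj);
        }
      }
      double c = x(i, j);
      for (int w = 1; w < center_weight; ++w) buf[k++] = c;
      std::nth_element(buf.begin(), buf.begin() + nsamp / 2, buf.end());
      out(i, j) = buf[nsamp / 2];
    }
  }
  return out;
}

// Connected-component labelling of a binary array, 8-connectivity in 2D and
// 26-connectivity in 3D. dims has length 2 or 3 (row, col[, slice]).
// Returns integer labels 1..n in first-encounter (column-major) order.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims) {
  int nd = dims.size();
  if (nd != 2 && nd != 3) stop("dims must have length 2 or 3");
  int nr = dims[0], nc = dims[1], ns = (nd == 3) ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)nr * nc * ns;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s0 = 0; s0 < n; ++s0) {
    if (mask[s0] == 0 || lab[s0] != 0) continue;
    lab[s0] = ++next;
    q.push(s0);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      int i = p % nr, j = (p / nr) % nc, k = p / ((R_xlen_t)nr * nc);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= ns) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nr) continue;
            R_xlen_t pp = ii + (R_xlen_t)nr * (jj + (R_xlen_t)nc * kk);
            if (mask[pp] != 0 && lab[pp] == 0) {
              lab[pp] = next;
              q.push(pp);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
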