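#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a 3D logical array.
// connectivity: 6 (faces) or 26 (faces+edges+corners). Labels start at 1,
// background is 0. Flood fill with an explicit stack.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(nn); // zero-initialized

  std::vector<int> off1, off2, off3;
  for (int dc = -1; dc <= 1; ++dc)
    for (int db = -1; db <= 1; ++db)
      for (int da = -1; da <= 1; ++da) {
        if (da == 0 && db == 0 && dc == 0) continue;
        int ad = std::abs(da) + std::abs(db) + std::abs(dc);
        if (connectivity == 6 && ad != 1) continue;
        off1.push_back(da); off2.push_back(db); off3.push_back(dc);
      }
  const int no = off1.size();

  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < nn; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int a = (int)(p % n1);
      int b = (int)((p / n1) % n2);
      int c = (int)(p / ((R_xlen_t)n1 * n2));
      for (int t = 0; t < no; ++t) {
        int aa = a + off1[t], bb = b + off2[t], cc = c + off3[t];
        if (aa < 0 || aa >= n1 || bb < 0 || bb >= n2 || cc < 0 || cc >= n3) continue;
        R_xlen_t q = aa + (R_xlen_t)n1 * (bb + (R_xlen_t)n2 * cc);
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("n") = cur;
  return lab;
}
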