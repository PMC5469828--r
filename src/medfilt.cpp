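#include <Rcpp.h>
using namespace Rcpp;

static inline int reflm(int i, int n) {
  if (n == 1) return 0;
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// Box median filter of a 3D array; radius per axis in voxels (0 allowed).
// Used to suppress thin LCN structures before cement-line (sheet) detection.
// [[Rcpp::export(name = ".median_filter3")]]
NumericVector median_filter3(NumericVector x, IntegerVector dim, IntegerVector radius) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int r1 = radius[0], r2 = radius[1], r3 = radius[2];
  NumericVector out(x.size());
  const int k = (2 * r1 + 1) * (2 * r2 + 1) * (2 * r3 + 1);
  std::vector<double> buf(k);
  const double* px = x.begin();
  for (int c = 0; c < n3; ++c)
    for (int b = 0; b < n2; ++b)
      for (int a = 0; a < n1; ++a) {
        int m = 0;
        for (int dc = -r3; dc <= r3; ++dc) {
          int cc = reflm(c + dc, n3);
          for (int db = -r2; db <= r2; ++db) {
            int bb = reflm(b + db, n2);
            for (int da = -r1; da <= r1; ++da) {
              int aa = reflm(a + da, n1);
              buf[m++] = px[aa + (R_xlen_t)n1 * (bb + (R_xlen_t)n2 * cc)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        double med = buf[k / 2];
        if (k % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + k / 2 - 1, buf.begin() + k / 2);
          med = 0.5 * (med + buf[k / 2 - 1]);
        }
        out[a + (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c)] = med;
      }
  return out;
}
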