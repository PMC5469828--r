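#include <Rcpp.h>
using namespace Rcpp;

// Reflective ("symmetric") boundary index: -1 -> 0, -2 -> 1, n -> n-1, ...
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Convolve a 3D array (column-major, dim = c(n1, n2, n3)) along one axis
// with a 1D kernel, reflective boundaries. axis: 0, 1 or 2 (R dims 1..3).
// [[Rcpp::export(name = ".conv3_axis")]]
NumericVector conv3_axis(NumericVector x, IntegerVector dim, NumericVector k, int axis) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int nk = k.size();
  const int hk = nk / 2; // kernel assumed odd length, centered
  NumericVector out(x.size());
  const double *px = x.begin(), *pk = k.begin();
  double *po = out.begin();

  const int nax = (axis == 0) ? n1 : (axis == 1) ? n2 : n3;
  std::vector<double> line(nax), res(nax);

  // iterate over all lines along `axis`
  if (axis == 0) {
    for (int c = 0; c < n3; ++c)
      for (int b = 0; b < n2; ++b) {
        const R_xlen_t base = (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c);
        for (int a = 0; a < n1; ++a) line[a] = px[base + a];
        for (int a = 0; a < n1; ++a) {
          double s = 0;
          for (int t = 0; t < nk; ++t) s += pk[t] * line[refl(a + t - hk, n1)];
          res[a] = s;
        }
        for (int a = 0; a < n1; ++a) po[base + a] = res[a];
      }
  } else if (axis == 1) {
    for (int c = 0; c < n3; ++c)
      for (int a = 0; a < n1; ++a) {
        const R_xlen_t base = a + (R_xlen_t)n1 * n2 * c;
        for (int b = 0; b < n2; ++b) line[b] = px[base + (R_xlen_t)n1 * b];
        for (int b = 0; b < n2; ++b) {
          double s = 0;
          for (int t = 0; t < nk; ++t) s += pk[t] * line[refl(b + t - hk, n2)];
          res[b] = s;
        }
        for (int b = 0; b < n2; ++b) po[base + (R_xlen_t)n1 * b] = res[b];
      }
  } else {
    const R_xlen_t st = (R_xlen_t)n1 * n2;
    for (int b = 0; b < n2; ++b)
      for (int a = 0; a < n1; ++a) {
        const R_xlen_t base = a + (R_xlen_t)n1 * b;
        for (int c = 0; c < n3; ++c) line[c] = px[base + st * c];
        for (int c = 0; c < n3; ++c) {
          double s = 0;
          for (int t = 0; t < nk; ++t) s += pk[t] * line[refl(c + t - hk, n3)];
          res[c] = s;
        }
        for (int c = 0; c < n3; ++c) po[base + st * c] = res[c];
      }
  }
  return out;
}
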