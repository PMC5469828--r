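#include <Rcpp.h>
using namespace Rcpp;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher), grid spacing w. f: input values; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (physical units) from every voxel to the
// nearest TRUE voxel of `mask`. dim = c(n1, n2, n3); spacing per dim.
// [[Rcpp::export(name = ".edt3_sq")]]
NumericVector edt3_sq(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  NumericVector D(nn);
  // large finite sentinel (not Inf: Inf - Inf = NaN breaks the parabola
  // intersection arithmetic and can underflow the envelope index)
  double L1 = n1 * spacing[0], L2 = n2 * spacing[1], L3 = n3 * spacing[2];
  const double BIG = 2.0 * (L1 * L1 + L2 * L2 + L3 * L3) + 1.0;
  for (R_xlen_t i = 0; i < nn; ++i) D[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int c = 0; c < n3; ++c)
    for (int b = 0; b < n2; ++b) {
      R_xlen_t base = (R_xlen_t)n1 * (b + (R_xlen_t)n2 * c);
      for (int a = 0; a < n1; ++a) f[a] = D[base + a];
      dt1d(f, d, n1, spacing[0], v, z);
      for (int a = 0; a < n1; ++a) D[base + a] = d[a];
    }
  // axis 2
  for (int c = 0; c < n3; ++c)
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base = a + (R_xlen_t)n1 * n2 * c;
      for (int b = 0; b < n2; ++b) f[b] = D[base + (R_xlen_t)n1 * b];
      dt1d(f, d, n2, spacing[1], v, z);
      for (int b = 0; b < n2; ++b) D[base + (R_xlen_t)n1 * b] = d[b];
    }
  // axis 3
  const R_xlen_t st = (R_xlen_t)n1 * n2;
  for (int b = 0; b < n2; ++b)
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base = a + (R_xlen_t)n1 * b;
      for (int c = 0; c < n3; ++c) f[c] = D[base + st * c];
      dt1d(f, d, n3, spacing[2], v, z);
      for (int c = 0; c < n3; ++c) D[base + st * c] = d[c];
    }
  return D;
}
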