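#include <Rcpp.h>
using namespace Rcpp;

static inline int reflr(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// in-place separable convolution (reflective), buf is scratch of same size
static void sep_conv3(std::vector<double>& x, const int* dim,
                      const std::vector<double>* ks, std::vector<double>& buf) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> line(nmax), res(nmax);
  for (int axis = 0; axis < 3; ++axis) {
    const std::vector<double>& k = ks[axis];
    const int nk = (int)k.size();
    if (nk <= 1) continue;
    const int hk = nk / 2;
    if (axis == 0) {
      for (int c = 0; c < n3; ++c)
        for (int b = 0; b < n2; ++b) {
          const size_t base = (size_t)n1 * (b + (size_t)n2 * c);
          for (int a = 0; a < n1; ++a) line[a] = x[base + a];
          for (int a = 0; a < n1; ++a) {
            double s = 0;
            for (int t = 0; t < nk; ++t) s += k[t] * line[reflr(a + t - hk, n1)];
            x[base + a] = s;
          }
        }
    } else if (axis == 1) {
      for (int c = 0; c < n3; ++c)
        for (int a = 0; a < n1; ++a) {
          const size_t base = a + (size_t)n1 * n2 * c;
          for (int b = 0; b < n2; ++b) line[b] = x[base + (size_t)n1 * b];
          for (int b = 0; b < n2; ++b) {
            double s = 0;
            for (int t = 0; t < nk; ++t) s += k[t] * line[reflr(b + t - hk, n2)];
            x[base + (size_t)n1 * b] = s;
          }
        }
    } else {
      const size_t st = (size_t)n1 * n2;
      for (int b = 0; b < n2; ++b)
        for (int a = 0; a < n1; ++a) {
          const size_t base = a + (size_t)n1 * b;
          for (int c = 0; c < n3; ++c) line[c] = x[base + st * c];
          for (int c = 0; c < n3; ++c) {
            double s = 0;
            for (int t = 0; t < nk; ++t) s += k[t] * line[reflr(c + t - hk, n3)];
            x[base + st * c] = s;
          }
        }
    }
  }
  (void)buf;
}

// Richardson-Lucy iterations for a separable symmetric PSF, fully in C++.
// [[Rcpp::export(name = ".rl_sep")]]
NumericVector rl_sep(NumericVector y, IntegerVector dim, NumericVector kz,
                     NumericVector ky, NumericVector kx, int n_iter,
                     double x0) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const size_t nn = (size_t)d[0] * d[1] * d[2];
  std::vector<double> ks[3];
  ks[0].assign(kz.begin(), kz.end());
  ks[1].assign(ky.begin(), ky.end());
  ks[2].assign(kx.begin(), kx.end());
  std::vector<double> x(nn, x0), work(nn), buf;
  const double eps = 1e-12;
  for (int it = 0; it < n_iter; ++it) {
    for (size_t i = 0; i < nn; ++i) work[i] = x[i];
    sep_conv3(work, d, ks, buf); // H x
    for (size_t i = 0; i < nn; ++i)
      work[i] = y[i] / std::max(work[i], eps);
    sep_conv3(work, d, ks, buf); // H^T ratio (symmetric kernels)
    for (size_t i = 0; i < nn; ++i) {
      x[i] *= work[i];
      if (x[i] < 0) x[i] = 0;
    }
  }
  NumericVector out(nn);
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}
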