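#include <Rcpp.h>
using namespace Rcpp;

static inline int reflh(int i, int n) {
  if (n == 1) return 0;
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// Eigenvalues of a symmetric 3x3 matrix (trigonometric method),
// returned unordered in l[0..2].
static void eig3sym(double a11, double a22, double a33,
                    double a12, double a13, double a23, double* l) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 == 0.0) { l[0] = a11; l[1] = a22; l[2] = a33; return; }
  double q = (a11 + a22 + a33) / 3.0;
  double b11 = a11 - q, b22 = a22 - q, b33 = a33 - q;
  double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  // det(B)/2 with B = (A - qI)/p
  double c11 = b11 / p, c22 = b22 / p, c33 = b33 / p;
  double c12 = a12 / p, c13 = a13 / p, c23 = a23 / p;
  double detB = c11 * (c22 * c33 - c23 * c23) - c12 * (c12 * c33 - c23 * c13)
              + c13 * (c12 * c23 - c22 * c13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  double e1 = q + 2.0 * p * std::cos(phi);
  double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  l[0] = e1; l[1] = 3.0 * q - e1 - e3; l[2] = e3;
}

// Scale-normalized Hessian eigen-analysis of a (pre-smoothed) volume.
// Returns, per voxel, the Frangi quantities with eigenvalues ordered
// |l1| <= |l2| <= |l3|:
//   ra = |l2|/|l3|, rb = |l1|/sqrt(|l2 l3|), s = sqrt(l1^2+l2^2+l3^2),
//   tube = (l2 < 0 && l3 < 0), sheet = (l3 < 0).
// Second derivatives are central differences in physical units (spacing,
// micrometres), multiplied by sigma^2 (gamma = 2 normalization).
// [[Rcpp::export(name = ".hessian_measures")]]
List hessian_measures(NumericVector sm, IntegerVector dim, NumericVector spacing,
                      double sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t nn = (R_xlen_t)n1 * n2 * n3;
  NumericVector ra(nn), rb(nn), s(nn);
  LogicalVector tube(nn), sheet(nn);
  const double h1 = spacing[0], h2 = spacing[1], h3 = spacing[2];
  const double s2 = sigma * sigma;
  const double *f = sm.begin();
  const R_xlen_t st2 = n1, st3 = (R_xlen_t)n1 * n2;

  for (int c = 0; c < n3; ++c) {
    int cm = reflh(c - 1, n3), cp = reflh(c + 1, n3);
    for (int b = 0; b < n2; ++b) {
      int bm = reflh(b - 1, n2), bp = reflh(b + 1, n2);
      for (int a = 0; a < n1; ++a) {
        int am = reflh(a - 1, n1), ap = reflh(a + 1, n1);
        R_xlen_t p = a + st2 * b + st3 * c;
        double f0 = f[p];
        double h11 = (f[ap + st2 * b + st3 * c] - 2 * f0 + f[am + st2 * b + st3 * c]) / (h1 * h1);
        double h22 = (f[a + st2 * bp + st3 * c] - 2 * f0 + f[a + st2 * bm + st3 * c]) / (h2 * h2);
        double h33 = (f[a + st2 * b + st3 * cp] - 2 * f0 + f[a + st2 * b + st3 * cm]) / (h3 * h3);
        double h12 = (f[ap + st2 * bp + st3 * c] - f[ap + st2 * bm + st3 * c]
                    - f[am + st2 * bp + st3 * c] + f[am + st2 * bm + st3 * c]) / (4 * h1 * h2);
        double h13 = (f[ap + st2 * b + st3 * cp] - f[ap + st2 * b + st3 * cm]
                    - f[am + st2 * b + st3 * cp] + f[am + st2 * b + st3 * cm]) / (4 * h1 * h3);
        double h23 = (f[a + st2 * bp + st3 * cp] - f[a + st2 * bp + st3 * cm]
                    - f[a + st2 * bm + st3 * cp] + f[a + st2 * bm + st3 * cm]) / (4 * h2 * h3);
        double l[3];
        eig3sym(s2 * h11, s2 * h22, s2 * h33, s2 * h12, s2 * h13, s2 * h23, l);
        // order by |.|
        double a0 = std::fabs(l[0]), a1 = std::fabs(l[1]), a2 = std::fabs(l[2]);
        double t;
        if (a0 > a1) { t = l[0]; l[0] = l[1]; l[1] = t; t = a0; a0 = a1; a1 = t; }
        if (a1 > a2) { t = l[1]; l[1] = l[2]; l[2] = t; t = a1; a1 = a2; a2 = t; }
        if (a0 > a1) { t = l[0]; l[0] = l[1]; l[1] = t; t = a0; a0 = a1; a1 = t; }
        double eps = 1e-12;
        ra[p] = a1 / (a2 + eps);
        rb[p] = a0 / (std::sqrt(a1 * a2) + eps);
        s[p] = std::sqrt(l[0] * l[0] + l[1] * l[1] + l[2] * l[2]);
        tube[p] = (l[1] < 0 && l[2] < 0);
        sheet[p] = (l[2] < 0);
      }
    }
  }
  return List::create(_["ra"] = ra, _["rb"] = rb, _["s"] = s,
                      _["tube"] = tube, _["sheet"] = sheet);
}
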