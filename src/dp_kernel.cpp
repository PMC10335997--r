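#include <Rcpp.h>
#include <cmath>

// Time-domain two-tone drive of a first-order Boltzmann transducer and
// extraction of the complex component at the distortion frequency fdp.
//
// For each drive j the input is
//   x(t) = A1[j] cos(2 pi f1 t + 2 pi ph1[j]) + A2[j] cos(2 pi f2 t + 2 pi ph2[j])
// (amplitudes are peak values, phases in cycles), the output is
//   y(t) = 1 / (1 + exp(a1 (x1 - x(t))))
// and the returned value is the complex peak amplitude of the fdp component,
//   (2/n) sum_t y(t) exp(-i 2 pi fdp t),
// exact for frequencies that complete an integer number of cycles in the
// n-sample window. Trigonometric factors are precomputed per sample so the
// inner loop costs one exp per sample per drive.
//
// [[Rcpp::export(name = ".dp_kernel")]]
Rcpp::ComplexVector dp_kernel(Rcpp::NumericVector A1, Rcpp::NumericVector ph1,
                              Rcpp::NumericVector A2, Rcpp::NumericVector ph2,
                              double f1, double f2, double fdp,
                              double fs, int n, double a1, double x1) {
  const int m = A1.size();
  if (ph1.size() != m || A2.size() != m || ph2.size() != m)
    Rcpp::stop("drive vectors must share a common length");
  const double two_pi = 2.0 * M_PI;

  std::vector<double> c1(n), s1(n), c2(n), s2(n), cd(n), sd(n);
  for (int t = 0; t < n; ++t) {
    const double tt = static_cast<double>(t) / fs;
    c1[t] = std::cos(two_pi * f1 * tt);
    s1[t] = std::sin(two_pi * f1 * tt);
    c2[t] = std::cos(two_pi * f2 * tt);
    s2[t] = std::sin(two_pi * f2 * tt);
    cd[t] = std::cos(two_pi * fdp * tt);
    sd[t] = std::sin(two_pi * fdp * tt);
  }

  Rcpp::ComplexVector out(m);
  for (int j = 0; j < m; ++j) {
    const double a1c = A1[j] * std::cos(two_pi * ph1[j]);
    const double a1s = A1[j] * std::sin(two_pi * ph1[j]);
    const double a2c = A2[j] * std::cos(two_pi * ph2[j]);
    const double a2s = A2[j] * std::sin(two_pi * ph2[j]);
    double accR = 0.0, accI = 0.0;
    for (int t = 0; t < n; ++t) {
      const double x = a1c * c1[t] - a1s * s1[t] + a2c * c2[t] - a2s * s2[t];
      const double y = 1.0 / (1.0 + std::exp(a1 * (x1 - x)));
      accR += y * cd[t];
      accI -= y * sd[t];
    }
    out[j].r = 2.0 * accR / n;
    out[j].i = 2.0 * accI / n;
  }
  return out;
}
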