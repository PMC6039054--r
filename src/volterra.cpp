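#include <Rcpp.h>
using namespace Rcpp;

// Product-integration forward sweep for the linear Volterra equation of the
// second kind
//    X(t) = b(t) + cfac * int_0^t X(s) k(t - s) ds
// on the uniform grid t_i = i * dt, i = 0..N. The unknown X is treated as
// piecewise linear between grid points while the (possibly integrably
// singular) kernel k enters only through its exact panel moments
//    m0[j] = int_{j dt}^{(j+1) dt} k(u) du
//    w1[j] = (1/dt) int_{j dt}^{(j+1) dt} (u - j dt) k(u) du
// so that int over panel j of X(t - u) k(u) du
//    = X_{n-j} (m0[j] - w1[j]) + X_{n-j-1} w1[j].
// b is given at t_1..t_N; x0 = X(0).
// [[Rcpp::export]]
NumericVector cpp_volterra_sweep(NumericVector b, NumericVector m0,
                                 NumericVector w1, double cfac, double x0) {
  const int N = b.size();
  std::vector<double> x(N + 1);
  x[0] = x0;
  std::vector<double> a(N), c(N);  // a[j] = m0[j]-w1[j], c[j] = w1[j]
  for (int j = 0; j < N; ++j) { a[j] = m0[j] - w1[j]; c[j] = w1[j]; }
  const double denom = 1.0 - cfac * a[0];
  for (int n = 1; n <= N; ++n) {
    double s = x[n - 1] * c[0];
    const double *xp = x.data();
    for (int j = 1; j < n; ++j) {
      s += xp[n - j] * a[j] + xp[n - j - 1] * c[j];
    }
    x[n] = (b[n - 1] + cfac * s) / denom;
  }
  NumericVector out(N);
  for (int n = 1; n <= N; ++n) out[n - 1] = x[n];
  return out;
}

// Product-integration convolution of a known piecewise-linear function X
// (values x at t_1..t_N, X(0) = x0) with a kernel given by its exact panel
// moments: returns c_n = int_0^{n dt} X(n dt - u) k(u) du for n = 1..N.
// [[Rcpp::export]]
NumericVector cpp_product_convolve(NumericVector x, double x0,
                                   NumericVector m0, NumericVector w1) {
  const int N = x.size();
  std::vector<double> xv(N + 1);
  xv[0] = x0;
  for (int i = 1; i <= N; ++i) xv[i] = x[i - 1];
  NumericVector out(N);
  for (int n = 1; n <= N; ++n) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      s += xv[n - j] * (m0[j] - w1[j]) + xv[n - j - 1] * w1[j];
    }
    out[n - 1] = s;
  }
  return out;
}
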