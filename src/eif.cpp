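#include <Rcpp.h>
#include <complex>
using namespace Rcpp;

// Threshold-integration solvers for integrate-and-fire first-passage
// statistics on a uniform voltage grid. The drift is
//   F(v) = mu - v + delta_T * exp((v - vT)/delta_T)   (EIF; delta_T > 0)
//   F(v) = mu - v                                     (LIF; delta_T == 0)
// with the exponential argument clipped at its threshold value to avoid
// overflow when delta_T is small.

static inline double drift(double v, double mu, double delta_T, double vT,
                           double arg_max) {
  if (delta_T > 0.0) {
    double arg = (v - vT) / delta_T;
    if (arg > arg_max) arg = arg_max;
    return mu - v + delta_T * std::exp(arg);
  }
  return mu - v;
}

// Steady-state firing rate: integrate the stationary density backward from
// the absorbing threshold with unit flux above the reset (delta re-injection
// at vre), zero flux below; rate = 1 / integral of the density.
// [[Rcpp::export]]
double cpp_if_steady_rate(double tau, double mu, double sigma, double vth,
                          double vre, double delta_T, double vT,
                          double dv, double vlb) {
  const double sig2 = sigma * sigma;
  const int K = (int)std::ceil((vth - vlb) / dv);
  const double h = (vth - vlb) / K;
  const double arg_max = delta_T > 0.0 ? (vth - vT) / delta_T : 0.0;
  double P = 0.0;        // density at current grid point (starts at vth)
  double integral = 0.0; // trapezoid accumulation of P
  double v = vth;
  for (int k = 0; k < K; ++k) {
    const double vm = v - 0.5 * h;          // panel midpoint
    const double J = (vm > vre) ? 1.0 : 0.0; // unit flux above reset
    const double Fm = drift(vm, mu, delta_T, vT, arg_max);
    double Pnew;
    if (std::fabs(Fm) * h / sig2 > 1e-10) {
      const double A = std::exp(-h * Fm / sig2);
      Pnew = (P - tau * J / Fm) * A + tau * J / Fm;
    } else {
      Pnew = P + h * tau * J / sig2;
    }
    integral += 0.5 * h * (P + Pnew);
    if (!std::isfinite(Pnew) || integral > 1e290) {
      return 0.0;  // density blows up below rheobase at vanishing noise
    }
    P = Pnew;
    v -= h;
  }
  return 1.0 / integral;
}

struct PJ {
  std::complex<double> p, j;
};

// one backward step of the Laplace-domain pair
//   dj/dv = -z p,   dp/dv = (F(v) p - tau j) / sigma^2
// using an integrating-factor update for p (exact for constant F, j) and a
// trapezoidal update for j, with one corrector pass.
static inline void step_down(PJ &s, double Fm, double h, double tau,
                             double sig2, std::complex<double> z) {
  const std::complex<double> p0 = s.p, j0 = s.j;
  std::complex<double> p1, j1;
  const bool stiff = std::fabs(Fm) * h / sig2 > 1e-10;
  const double A = stiff ? std::exp(-h * Fm / sig2) : 1.0;
  // predictor with j held at j0
  if (stiff) p1 = (p0 - tau * j0 / Fm) * A + tau * j0 / Fm;
  else       p1 = p0 + h * (Fm * p0 - tau * j0) / sig2;
  j1 = j0 + 0.5 * h * z * (p0 + p1);
  // corrector with midpoint j
  const std::complex<double> jm = 0.5 * (j0 + j1);
  if (stiff) p1 = (p0 - tau * jm / Fm) * A + tau * jm / Fm;
  else       p1 = p0 + h * (Fm * p0 - tau * jm) / sig2;
  j1 = j0 + 0.5 * h * z * (p0 + p1);
  s.p = p1;
  s.j = j1;
}

// Laplace transform L(z) of the first-passage-time density from vre to vth,
// by backward threshold integration: one solution launched at the absorbing
// threshold with unit flux, a second at the reset (the delta re-injection);
// requiring decay at the lower bound gives L as the flux ratio there.
// Supports complex z (zim != 0) for Fourier-domain evaluation.
// [[Rcpp::export]]
ComplexVector cpp_if_fpt_laplace(double tau, double mu, double sigma,
                                 double vth, double vre, double delta_T,
                                 double vT, double dv, double vlb,
                                 double zre, double zim) {
  const double sig2 = sigma * sigma;
  const std::complex<double> z(zre, zim);
  const double arg_max = delta_T > 0.0 ? (vth - vT) / delta_T : 0.0;

  // grid: vth down to vlb, reset snapped to the grid
  const int K = (int)std::ceil((vth - vlb) / dv);
  const double h = (vth - vlb) / K;
  int kre = (int)std::llround((vth - vre) / h);
  if (kre < 1) kre = 1;
  if (kre > K - 1) kre = K - 1;

  PJ s1; s1.p = 0.0; s1.j = 1.0;  // from the threshold
  double logscale1 = 0.0;

  double v = vth;
  for (int k = 0; k < kre; ++k) {
    const double vm = v - 0.5 * h;
    step_down(s1, drift(vm, mu, delta_T, vT, arg_max), h, tau, sig2, z);
    v -= h;
    const double m = std::abs(s1.j) + std::abs(s1.p);
    if (m > 1e100 || (m > 0 && m < 1e-100)) {
      s1.p /= m; s1.j /= m; logscale1 += std::log(m);
    }
  }

  PJ s2; s2.p = 0.0; s2.j = 1.0;  // re-injection at the reset
  for (int k = kre; k < K; ++k) {
    const double vm = v - 0.5 * h;
    const double Fm = drift(vm, mu, delta_T, vT, arg_max);
    step_down(s1, Fm, h, tau, sig2, z);
    step_down(s2, Fm, h, tau, sig2, z);
    v -= h;
    const double m = std::abs(s1.j) + std::abs(s1.p);
    if (m > 1e100 || (m > 0 && m < 1e-100)) {
      s1.p /= m; s1.j /= m; s2.p /= m; s2.j /= m;
      // joint rescale cancels in the ratio; logscale1 unchanged
    }
  }

  const std::complex<double> L = (s2.j / s1.j) * std::exp(-logscale1);
  ComplexVector out(1);
  out[0] = Rcomplex{L.real(), L.imag()};
  return out;
}
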