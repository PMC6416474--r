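// Macroscopic PDT photokinetics: coupled rate equations for ground-state
// photosensitizer [S0], ground-state oxygen [3O2] and cumulative reacted
// singlet oxygen [1O2]rx under a constant fluence rate phi.
//
//   d[S0]/dt    = -xi sigma phi ([S0]+delta) ([3O2]/([3O2]+beta)) [S0]
//   d[3O2]/dt   = -xi phi [S0] ([3O2]/([3O2]+beta)) + g (1 - [3O2]/[3O2]_0)
//   d[1O2]rx/dt =  xi phi [S0] ([3O2]/([3O2]+beta))
//
// Units: concentrations uM, phi mW/cm2, xi cm2 mW^-1 s^-1, so rates are uM/s.
// Integrated with an embedded Dormand-Prince RK5(4) pair; any step whose
// 5th-order result has a negative component is rejected and halved, keeping
// the solution non-negative without losing order away from the boundary.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

struct PkPar {
  double g, delta, beta, sigma, xi, o2init;
};

static inline void rhs(const double* y, double phi, const PkPar& p,
                       double* dy) {
  double frac = y[1] / (y[1] + p.beta);
  double rx = p.xi * phi * y[0] * frac;
  dy[0] = -p.xi * p.sigma * phi * (y[0] + p.delta) * frac * y[0];
  dy[1] = -rx + p.g * (1.0 - y[1] / p.o2init);
  dy[2] = rx;
}

// Dormand-Prince coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
// 4th-order (embedded) weights
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

static const double NEG_CLAMP = 1e-12;  // uM; magnitudes below snap to zero

// Integrate one voxel; returns 0 on success, 1 on step-size underflow.
// If `times`/`states` are non-null, accepted steps are recorded.
static int integrate_one(double phi, double s0, const PkPar& p, double T,
                         double rtol, double atol, double h0,
                         double* yfinal, std::vector<double>* times,
                         std::vector<double>* states) {
  double y[3] = {s0, p.o2init, 0.0};
  double t = 0.0;
  double h = h0;
  if (times) {
    times->push_back(0.0);
    states->insert(states->end(), y, y + 3);
  }
  if (T <= 0.0 || (phi <= 0.0 && std::fabs(y[1] - p.o2init) < 1e-300)) {
    // dark start at the oxygen fixed point: nothing evolves
    yfinal[0] = y[0]; yfinal[1] = y[1]; yfinal[2] = y[2];
    return 0;
  }
  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], yt[3], ynew[3];
  rhs(y, phi, p, k1);  // FSAL
  const double hmin = 1e-12;
  while (t < T) {
    if (h > T - t) h = T - t;
    yt[0] = y[0] + h * A21 * k1[0];
    yt[1] = y[1] + h * A21 * k1[1];
    yt[2] = y[2] + h * A21 * k1[2];
    rhs(yt, phi, p, k2);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    rhs(yt, phi, p, k3);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    rhs(yt, phi, p, k4);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                          A54 * k4[i]);
    rhs(yt, phi, p, k5);
    for (int i = 0; i < 3; ++i)
      yt[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                          A64 * k4[i] + A65 * k5[i]);
    rhs(yt, phi, p, k6);
    for (int i = 0; i < 3; ++i)
      ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                            B5 * k5[i] + B6 * k6[i]);
    rhs(ynew, phi, p, k7);

    bool neg = false;
    for (int i = 0; i < 3; ++i) {
      if (ynew[i] < -NEG_CLAMP) neg = true;
    }
    double err = 0.0;
    for (int i = 0; i < 3; ++i) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double q = e / sc;
      err += q * q;
    }
    err = std::sqrt(err / 3.0);

    if (err <= 1.0 && !neg) {
      t += h;
      for (int i = 0; i < 3; ++i) {
        y[i] = ynew[i];
        if (y[i] < 0.0) y[i] = 0.0;  // clamp |y| < NEG_CLAMP undershoot
        k1[i] = k7[i];
      }
      if (times) {
        times->push_back(t);
        states->insert(states->end(), y, y + 3);
      }
      double fac = err > 0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else if (neg) {
      h *= 0.5;  // reject: step crossed the non-negativity boundary
    } else {
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
    }
    if (h < hmin) return 1;
  }
  yfinal[0] = y[0]; yfinal[1] = y[1]; yfinal[2] = y[2];
  return 0;
}

// [[Rcpp::export]]
List cpp_integrate_pk(double phi, double s0, List params, double T,
                      double rtol, double atol, double h0, bool trajectory) {
  PkPar p{as<double>(params["g"]), as<double>(params["delta"]),
          as<double>(params["beta"]), as<double>(params["sigma"]),
          as<double>(params["xi"]), as<double>(params["O2_initial"])};
  double yf[3];
  std::vector<double> times, states;
  int status = integrate_one(phi, s0, p, T, rtol, atol, h0, yf,
                             trajectory ? &times : nullptr,
                             trajectory ? &states : nullptr);
  List out = List::create(
    _["S0"] = yf[0], _["O2"] = yf[1], _["O2rx"] = yf[2],
    _["status"] = status);
  if (trajectory) {
    int ns = times.size();
    NumericMatrix st(ns, 3);
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < 3; ++j) st(i, j) = states[3 * i + j];
    out["times"] = NumericVector(times.begin(), times.end());
    out["states"] = st;
  }
  return out;
}

// Per-voxel dose over a fluence vector.  s0 is recycled if length 1.
// Returns the reacted singlet oxygen concentration (uM) per voxel.
// [[Rcpp::export]]
NumericVector cpp_dose_vec(NumericVector phi, NumericVector s0, List params,
                           double T, double rtol, double atol, double h0) {
  PkPar p{as<double>(params["g"]), as<double>(params["delta"]),
          as<double>(params["beta"]), as<double>(params["sigma"]),
          as<double>(params["xi"]), as<double>(params["O2_initial"])};
  R_xlen_t n = phi.size();
  bool s0scalar = s0.size() == 1;
  NumericVector out(n);
  double yf[3];
  for (R_xlen_t v = 0; v < n; ++v) {
    double f = phi[v];
    if (f <= 0.0) { out[v] = 0.0; continue; }
    int status = integrate_one(f, s0scalar ? s0[0] : s0[v], p, T, rtol, atol,
                               h0, yf, nullptr, nullptr);
    if (status != 0)
      stop("photokinetic integration failed at voxel %d (step underflow)",
           (int)(v + 1));
    out[v] = yf[2];
    if ((v & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
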