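// Core integrator for the coupled sleep-wake / circadian / phototransduction
// system.  Light is piecewise-constant per recording epoch and gated by the
// model's own wake state (eyes-closed masking), so the integrator restarts at
// every epoch boundary and the step size never exceeds one epoch.
//
// State vector: V_v (sleep-active voltage, mV), V_m (wake-active voltage, mV),
// H (homeostatic pressure), x, x_c (pacemaker), n (photoreceptor fraction).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double tauC, deltaD;
  double Qmax, theta, sigma;
  double tauVh, tauMh;            // population time constants, hours
  double nuVM, nuMV, nuVH, nuVC;
  double Av, Am;
  double chi, mu;
  double alpha0, beta;            // per-minute rates
  double I0, pexp;
  double G, k, b, q, mup, f;
  double phiC;              // phase delay (h) of the circadian wake drive
};

static Pars unpack(const NumericVector& p) {
  Pars q;
  q.tauC = p[0]; q.deltaD = p[1];
  q.Qmax = p[2]; q.theta = p[3]; q.sigma = p[4];
  q.tauVh = p[5] / 3600.0; q.tauMh = p[6] / 3600.0;  // given in seconds
  q.nuVM = p[7]; q.nuMV = p[8]; q.nuVH = p[9]; q.nuVC = p[10];
  q.Av = p[11]; q.Am = p[12];
  q.chi = p[13]; q.mu = p[14];
  q.alpha0 = p[15]; q.beta = p[16];
  q.I0 = p[17]; q.pexp = p[18];
  q.G = p[19]; q.k = p[20]; q.b = p[21]; q.q = p[22];
  q.mup = p[23]; q.f = p[24];
  q.phiC = (p.size() > 25) ? p[25] : 0.0;
  return q;
}

// positive remainder without std::fmod (keeps the object portable across
// glibc symbol versions)
static inline double mod24(double t) {
  return t - 24.0 * std::floor(t / 24.0);
}

static inline double firingRate(double V, const Pars& p) {
  return p.Qmax / (1.0 + std::exp(-(V - p.theta) / p.sigma));
}

// alpha is the photic activation rate for the light level currently reaching
// the retina; it is constant within an integration step.
static inline void rhs(const double* y, double* dy, const Pars& p,
                       double alpha) {
  const double Vv = y[0], Vm = y[1], H = y[2];
  const double x = y[3], xc = y[4], n = y[5];
  const double Qv = firingRate(Vv, p);
  const double Qm = firingRate(Vm, p);
  const double ph = p.phiC * M_PI / 12.0;
  const double C = 0.5 * (1.0 + x * std::cos(ph) - xc * std::sin(ph));
  const double Dv = p.Av - p.deltaD + p.nuVH * H + p.nuVC * C;
  dy[0] = (p.nuVM * Qm + Dv - Vv) / p.tauVh;
  dy[1] = (p.nuMV * Qv + p.Am - Vm) / p.tauMh;
  dy[2] = (p.mu * Qm - H) / p.chi;
  const double B = p.G * alpha * (1.0 - n) * (1.0 - p.b * x) *
                   (1.0 - p.b * xc);
  dy[5] = 60.0 * (alpha * (1.0 - n) - p.beta * n);
  const double x3 = x * x * x;
  const double x7 = x3 * x3 * x;
  const double vdp = p.mup * (x / 3.0 + 4.0 * x3 / 3.0 - 256.0 * x7 / 105.0);
  const double pi12 = M_PI / 12.0;
  const double om = 24.0 / (p.f * p.tauC);
  dy[3] = pi12 * (xc + vdp + B);
  dy[4] = pi12 * (p.q * B * xc - x * (om * om + p.k * B));
}

// Cash-Karp embedded Runge-Kutta 4(5) coefficients.
static const double b21 = 0.2;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                    c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                    dc6 = c6 - 0.25;

#define NS 6

// One Cash-Karp step from y over h; y5 gets the 5th-order solution, returns
// the max scaled error estimate.
static double ckStep(const double* y, double h, const Pars& p, double alpha,
                     const double* dy1, double* y5, double rtol, double atol) {
  double k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], tmp[NS];
  for (int i = 0; i < NS; ++i) tmp[i] = y[i] + h * b21 * dy1[i];
  rhs(tmp, k2, p, alpha);
  for (int i = 0; i < NS; ++i)
    tmp[i] = y[i] + h * (b31 * dy1[i] + b32 * k2[i]);
  rhs(tmp, k3, p, alpha);
  for (int i = 0; i < NS; ++i)
    tmp[i] = y[i] + h * (b41 * dy1[i] + b42 * k2[i] + b43 * k3[i]);
  rhs(tmp, k4, p, alpha);
  for (int i = 0; i < NS; ++i)
    tmp[i] = y[i] + h * (b51 * dy1[i] + b52 * k2[i] + b53 * k3[i] +
                         b54 * k4[i]);
  rhs(tmp, k5, p, alpha);
  for (int i = 0; i < NS; ++i)
    tmp[i] = y[i] + h * (b61 * dy1[i] + b62 * k2[i] + b63 * k3[i] +
                         b64 * k4[i] + b65 * k5[i]);
  rhs(tmp, k6, p, alpha);
  double err = 0.0;
  for (int i = 0; i < NS; ++i) {
    y5[i] = y[i] + h * (c1 * dy1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
    const double ei = h * (dc1 * dy1[i] + dc3 * k3[i] + dc4 * k4[i] +
                           dc5 * k5[i] + dc6 * k6[i]);
    const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                             std::fabs(y5[i]));
    const double e = std::fabs(ei) / sc;
    if (e > err) err = e;
  }
  return err;
}

static inline double alphaOf(double I, const Pars& p) {
  if (I <= 0.0) return 0.0;
  return p.alpha0 * std::pow(I / p.I0, p.pexp);
}

// [[Rcpp::export(name = ".simulateCore")]]
List simulateCore(NumericVector y0, double t0, int nEpochs, double epochLen,
                  NumericVector pars, int lightMode, NumericVector lux,
                  NumericVector profilePar, NumericVector dayShift,
                  double rtol = 1e-6, double atol = 1e-8) {
  const Pars p = unpack(pars);
  if (y0.size() != NS) stop("state vector must have 6 components");
  double y[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];

  NumericMatrix states(nEpochs + 1, NS);
  LogicalVector wakeAt(nEpochs + 1);
  NumericVector received(nEpochs);   // time-mean lux actually reaching retina
  std::vector<double> transT;
  std::vector<int> transDir;         // +1 sleep->wake, -1 wake->sleep

  const bool profileMode = (lightMode == 1);
  const double Lday = profileMode ? profilePar[0] : 0.0;
  const double Leve = profileMode ? profilePar[1] : 0.0;
  const double rise = profileMode ? profilePar[2] : 0.0;
  const double peak = profileMode ? profilePar[3] : 0.0;
  const double decl = profileMode ? profilePar[4] : 0.0;
  const int nShift = dayShift.size();

  for (int i = 0; i < NS; ++i) states(0, i) = y[i];
  wakeAt[0] = y[1] > y[0];

  const double hmin = 1e-6;  // hours; ~3.6 ms
  double h = epochLen;

  for (int e = 0; e < nEpochs; ++e) {
    const double te0 = t0 + e * epochLen;
    const double te1 = te0 + epochLen;
    // available light for this epoch
    double avail;
    if (profileMode) {
      const double tm = te0 + 0.5 * epochLen;
      const int day = (int)std::floor(tm / 24.0);
      const double sh = (nShift > 0) ? dayShift[day % nShift] : 0.0;
      double ck = mod24(tm - sh);
      double L;
      if (ck <= rise || ck >= decl) {
        L = Leve;
      } else if (ck <= peak) {
        L = Leve + (Lday - Leve) *
            0.5 * (1.0 - std::cos(M_PI * (ck - rise) / (peak - rise)));
      } else {
        L = Leve + (Lday - Leve) *
            0.5 * (1.0 + std::cos(M_PI * (ck - peak) / (decl - peak)));
      }
      avail = L;
    } else {
      avail = lux[e];
    }
    const double alphaOn = alphaOf(avail, p);

    double t = te0;
    double luxTime = 0.0;  // integral of received lux over epoch
    while (t < te1 - 1e-12) {
      if (h > te1 - t) h = te1 - t;
      bool wake = y[1] > y[0];
      const double alpha = wake ? alphaOn : 0.0;
      double dy1[NS], y5[NS];
      rhs(y, dy1, p, alpha);
      double err = ckStep(y, h, p, alpha, dy1, y5, rtol, atol);
      if (err > 1.0) {
        // reject: shrink and retry
        double fac = 0.9 * std::pow(err, -0.25);
        if (fac < 0.1) fac = 0.1;
        h *= fac;
        if (h < hmin) h = hmin;
        if (h <= hmin) {
          // accept at hmin regardless to guarantee progress
          ckStep(y, h, p, alpha, dy1, y5, rtol, atol);
          err = 0.0;
        } else {
          continue;
        }
      }
      // accepted
      const double d0 = y[1] - y[0];
      const double d1 = y5[1] - y5[0];
      if ((d0 > 0) != (d1 > 0)) {
        // wake/sleep transition inside this step: locate by linear
        // interpolation of V_m - V_v (refined below 1 s by the small h that
        // error control forces during flip-flop switches)
        double frac = d0 / (d0 - d1);
        if (frac < 0) frac = 0;
        if (frac > 1) frac = 1;
        transT.push_back(t + frac * h);
        transDir.push_back(d1 > 0 ? 1 : -1);
        luxTime += (wake ? avail : 0.0) * frac * h +
                   (d1 > 0 ? avail : 0.0) * (1.0 - frac) * h;
      } else {
        luxTime += (wake ? avail : 0.0) * h;
      }
      for (int i = 0; i < NS; ++i) y[i] = y5[i];
      if (!std::isfinite(y[0]) || !std::isfinite(y[3]))
        stop("numerical failure: non-finite state at t = %f h", t);
      t += h;
      double fac = (err > 1e-12) ? 0.9 * std::pow(err, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
      if (h > epochLen) h = epochLen;
      if (h < hmin) h = hmin;
    }
    for (int i = 0; i < NS; ++i) states(e + 1, i) = y[i];
    wakeAt[e + 1] = y[1] > y[0];
    received[e] = luxTime / epochLen;
  }

  return List::create(
      _["states"] = states, _["wakeAt"] = wakeAt,
      _["received"] = received,
      _["transitionTimes"] = NumericVector(transT.begin(), transT.end()),
      _["transitionDir"] = IntegerVector(transDir.begin(), transDir.end()));
}

// [[Rcpp::export(name = ".derivativesCore")]]
NumericVector derivativesCore(NumericVector y, NumericVector pars, double I,
                              bool wake = true) {
  const Pars p = unpack(pars);
  if (y.size() != NS) stop("state vector must have 6 components");
  double yy[NS], dy[NS];
  for (int i = 0; i < NS; ++i) yy[i] = y[i];
  const double alpha = wake ? alphaOf(I, p) : 0.0;
  rhs(yy, dy, p, alpha);
  NumericVector out(NS);
  for (int i = 0; i < NS; ++i) out[i] = dy[i];
  return out;
}
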