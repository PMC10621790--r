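// Reduced warfarin PKPD core: one-compartment PK with first-order absorption
// feeding an inhibitory Hill effect on the production of a transit chain of
// clotting activity. Integrated with an adaptive Dormand-Prince 5(4) stepper;
// dose events are instantaneous bolus additions to the dose compartment and
// the daily occasion multiplier eta is piecewise constant over calendar days.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// psi layout (fixed, mirrored by R side):
// 0 ka, 1 ke, 2 V, 3 EC50, 4 gamma, 5 MTT, 6 n_transit, 7 inr_base,
// 8 inr_max, 9 lam
struct WfModel {
  double ka, ke, V, ec50, gamma, mtt, inr_base, inr_max, lam;
  int n_transit;
  int nstate() const { return 2 + n_transit; }
  // eta is the vitamin-K input multiplier in force for the current day
  void rhs(const double* y, double eta, double* dy) const {
    const double ad = y[0], ac = y[1];
    dy[0] = -ka * ad;
    dy[1] = ka * ad - ke * ac;
    double conc = ac / V;
    if (conc < 0.0) conc = 0.0;
    double cg = std::pow(conc, gamma);
    double effect = 1.0 - cg / (std::pow(ec50, gamma) + cg);
    const double ktr = n_transit / mtt;
    dy[2] = ktr * (eta * effect - y[2]);
    for (int i = 1; i < n_transit; ++i)
      dy[2 + i] = ktr * (y[1 + i] - y[2 + i]);
  }
  double inr(const double* y) const {
    double dep = 1.0 - y[1 + n_transit];
    if (dep < 0.0) dep = 0.0;
    return inr_base + inr_max * std::pow(dep, lam);
  }
};

static WfModel unpack(const NumericVector& psi) {
  if (psi.size() < 10) stop("psi must have 10 entries");
  WfModel m;
  m.ka = psi[0]; m.ke = psi[1]; m.V = psi[2]; m.ec50 = psi[3];
  m.gamma = psi[4]; m.mtt = psi[5]; m.n_transit = (int)std::lround(psi[6]);
  m.inr_base = psi[7]; m.inr_max = psi[8]; m.lam = psi[9];
  if (m.n_transit < 1) stop("n_transit must be >= 1");
  return m;
}

[[noreturn]] static void fail_integration(const WfModel& m, double t) {
  stop("ODE integration failed (non-finite state) at t=%.3f h for parameter "
       "set ka=%.4g ke=%.4g V=%.4g EC50=%.4g gamma=%.4g MTT=%.4g",
       t, m.ka, m.ke, m.V, m.ec50, m.gamma, m.mtt);
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// integrate y over [t0, t1] with constant eta (no events inside the span)
static void integrate_span(const WfModel& m, std::vector<double>& y,
                           double t0, double t1, double eta,
                           double rtol, double atol, double& hkeep) {
  const int n = m.nstate();
  if (t1 <= t0) return;
  double t = t0;
  double h = std::min(hkeep, t1 - t0);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), ynew(n);
  m.rhs(y.data(), eta, k1.data());  // FSAL seed
  int iter = 0;
  while (t < t1) {
    if (++iter > 1000000) fail_integration(m, t);
    if (h < 1e-12) fail_integration(m, t);
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    m.rhs(ytmp.data(), eta, k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    m.rhs(ytmp.data(), eta, k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    m.rhs(ytmp.data(), eta, k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    m.rhs(ytmp.data(), eta, k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    m.rhs(ytmp.data(), eta, k6.data());
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    m.rhs(ynew.data(), eta, k7.data());
    double err = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                      e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);
    if (!std::isfinite(err)) fail_integration(m, t);
    if (err <= 1.0) {
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(y[i])) fail_integration(m, t);
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    hkeep = h;  // persist the step size across spans
  }
}

// advance state through [t0, t1], applying dose boluses at dose times and
// switching eta at day boundaries (day k = [24k, 24(k+1)), 0-based; eta[k]
// applies, the last entry is reused beyond the end of the vector)
static void advance(const WfModel& m, std::vector<double>& y,
                    double t0, double t1,
                    const std::vector<double>& dose_t,
                    const std::vector<double>& dose_amt,
                    const NumericVector& eta,
                    double rtol, double atol, double& hkeep) {
  if (t1 <= t0) return;  // empty span: no integration, no (re-)dosing
  // collect breakpoints: dose times and, when eta varies, day boundaries
  std::vector<double> brk;
  for (size_t j = 0; j < dose_t.size(); ++j)
    if (dose_t[j] > t0 && dose_t[j] <= t1) brk.push_back(dose_t[j]);
  if (eta.size() > 1)
    for (double d = std::floor(t0 / 24.0) * 24.0 + 24.0; d < t1; d += 24.0)
      if (d > t0) brk.push_back(d);
  brk.push_back(t1);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end()), brk.end());

  // boluses exactly at t0 (start of this span) were applied by the caller
  double t = t0;
  for (double tb : brk) {
    int day = (int)std::floor((t + 1e-9) / 24.0);
    double et = 1.0;
    if (eta.size() > 0) {
      int idx = std::min(std::max(day, 0), (int)eta.size() - 1);
      et = eta[idx];
    }
    integrate_span(m, y, t, tb, et, rtol, atol, hkeep);
    t = tb;
    for (size_t j = 0; j < dose_t.size(); ++j)
      if (std::fabs(dose_t[j] - tb) < 1e-9) y[0] += dose_amt[j];
  }
}

// [[Rcpp::export]]
NumericMatrix wf_simulate_cpp(NumericVector psi, NumericVector dose_amt,
                              NumericVector dose_t, NumericVector eta,
                              NumericVector times, double rtol, double atol) {
  WfModel m = unpack(psi);
  if (times.size() == 0) stop("empty time grid");
  const int n = m.nstate();
  std::vector<double> y(n, 0.0);
  for (int i = 0; i < m.n_transit; ++i) y[2 + i] = 1.0;  // baseline activity
  std::vector<double> dt(dose_t.begin(), dose_t.end());
  std::vector<double> da(dose_amt.begin(), dose_amt.end());

  double t = std::min(0.0, times[0]);
  if (!dt.empty()) t = std::min(t, dt[0]);
  // apply any bolus scheduled exactly at the start
  for (size_t j = 0; j < dt.size(); ++j)
    if (std::fabs(dt[j] - t) < 1e-9) y[0] += da[j];

  NumericMatrix out(times.size(), 2);
  double hkeep = 1.0;
  for (int i = 0; i < times.size(); ++i) {
    if (i > 0 && times[i] < times[i - 1]) stop("times must be sorted");
    advance(m, y, t, times[i], dt, da, eta, rtol, atol, hkeep);
    t = std::max(t, (double)times[i]);
    double conc = y[1] / m.V;
    out(i, 0) = conc < 0.0 ? 0.0 : conc;
    out(i, 1) = m.inr(y.data());
  }
  return out;
}

// advance an explicit state vector; used for stateful day-by-day trial loops
// [[Rcpp::export]]
NumericVector wf_step_cpp(NumericVector state, NumericVector psi,
                          double t0, double t1, NumericVector dose_amt,
                          NumericVector dose_t, NumericVector eta,
                          double rtol, double atol) {
  WfModel m = unpack(psi);
  if ((int)state.size() != m.nstate())
    stop("state has wrong length (expected %d)", m.nstate());
  std::vector<double> y(state.begin(), state.end());
  std::vector<double> dt(dose_t.begin(), dose_t.end());
  std::vector<double> da(dose_amt.begin(), dose_amt.end());
  for (size_t j = 0; j < dt.size(); ++j)
    if (std::fabs(dt[j] - t0) < 1e-9) y[0] += da[j];
  double hkeep = 1.0;
  advance(m, y, t0, t1, dt, da, eta, rtol, atol, hkeep);
  return NumericVector(y.begin(), y.end());
}

// [[Rcpp::export]]
double wf_inr_cpp(NumericVector state, NumericVector psi) {
  WfModel m = unpack(psi);
  std::vector<double> y(state.begin(), state.end());
  return m.inr(y.data());
}
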