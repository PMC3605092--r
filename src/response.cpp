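// Adaptive Dormand-Prince 5(4) integration of the two-allele negative-
// autoregulation model with settle-time (band exit) detection. This is the
// production path for response-time experiments; the deSolve-based R path
// serves as the independent numerical oracle in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  int n;                       // ploidy (number of alleles)
  double bb, br, al, dm, dp;   // beta_b, beta_r, alpha, delta_m, delta_p
  std::vector<double> K, h;

  inline double hill(double P, int i) const {
    if (P <= 0.0) return 1.0;
    if (h[i] == 1.0) return 1.0 / (1.0 + P / K[i]);
    return 1.0 / (1.0 + std::pow(P / K[i], h[i]));
  }
  // y = (m_1..m_n, p_1..p_n)
  inline void rhs(const double* y, double* dy) const {
    double P = 0.0;
    for (int i = 0; i < n; ++i) P += y[n + i];
    for (int i = 0; i < n; ++i) {
      dy[i]     = bb + br * hill(P, i) - dm * y[i];
      dy[n + i] = al * y[i] - dp * y[n + i];
    }
  }
};

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
// error weights (5th minus embedded 4th order)
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

struct Stepper {
  const Model& M;
  int d;
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, tmp, err;
  explicit Stepper(const Model& m)
      : M(m), d(2 * m.n), k1(d), k2(d), k3(d), k4(d), k5(d), k6(d), k7(d),
        tmp(d), err(d) {}

  // attempt one step; fills ynew and the error estimate; k1 must hold f(y)
  void step(const double* y, double h, double* ynew) {
    for (int j = 0; j < d; ++j) tmp[j] = y[j] + h * a21 * k1[j];
    M.rhs(tmp.data(), k2.data());
    for (int j = 0; j < d; ++j)
      tmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    M.rhs(tmp.data(), k3.data());
    for (int j = 0; j < d; ++j)
      tmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    M.rhs(tmp.data(), k4.data());
    for (int j = 0; j < d; ++j)
      tmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                           a54 * k4[j]);
    M.rhs(tmp.data(), k5.data());
    for (int j = 0; j < d; ++j)
      tmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                           a64 * k4[j] + a65 * k5[j]);
    M.rhs(tmp.data(), k6.data());
    for (int j = 0; j < d; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    M.rhs(ynew, k7.data());
    for (int j = 0; j < d; ++j)
      err[j] = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                    e6 * k6[j] + e7 * k7[j]);
  }
};

// Cubic Hermite crossing of signal s(t) through level `lev` within [t0, t0+h],
// given endpoint values/derivatives. Bisection on the interpolant.
inline double hermite_cross(double t0, double h, double s0, double sd0,
                            double s1, double sd1, double lev) {
  double lo = 0.0, hi = 1.0;
  double flo = s0 - lev;
  for (int it = 0; it < 60; ++it) {
    double u = 0.5 * (lo + hi);
    double u2 = u * u, u3 = u2 * u;
    double val = (2 * u3 - 3 * u2 + 1) * s0 + (u3 - 2 * u2 + u) * h * sd0 +
                 (-2 * u3 + 3 * u2) * s1 + (u3 - u2) * h * sd1 - lev;
    if ((val > 0) == (flo > 0)) lo = u; else hi = u;
  }
  return t0 + 0.5 * (lo + hi) * h;
}

struct BandTracker {
  double target, width;        // band: |s - target| <= width
  double last_cross;           // most recent entry time into the band
  double last_outside;         // most recent node time seen outside the band
  bool ever_outside;
  void init(double tgt, double w, double s0) {
    target = tgt; width = w; last_cross = 0.0; last_outside = -1.0;
    ever_outside = std::abs(s0 - tgt) > w;
    if (ever_outside) last_outside = 0.0;
  }
  // update with step [t, t+h]; endpoint values s0 -> s1, derivatives sd0, sd1
  void update(double t, double h, double s0, double sd0, double s1, double sd1) {
    bool out0 = std::abs(s0 - target) > width;
    bool out1 = std::abs(s1 - target) > width;
    if (out1) { last_outside = t + h; ever_outside = true; return; }
    if (out0) {
      double lev = (s0 < target) ? target - width : target + width;
      last_cross = hermite_cross(t, h, s0, sd0, s1, sd1, lev);
    }
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".rt_settle_cpp")]]
NumericVector rt_settle_cpp(NumericVector y0, NumericVector K, NumericVector h,
                            double beta_b, double beta_r, double alpha,
                            double delta_m, double delta_p,
                            double P_eq, NumericVector p_allele_eq,
                            NumericVector scale, double theta,
                            double hmax, double rtol, double horizon,
                            double confirm, bool track_alleles) {
  Model M;
  M.n = K.size();
  M.bb = beta_b; M.br = beta_r; M.al = alpha; M.dm = delta_m; M.dp = delta_p;
  M.K.assign(K.begin(), K.end());
  M.h.assign(h.begin(), h.end());
  const int d = 2 * M.n;
  if (y0.size() != d || scale.size() != d)
    stop("state dimension does not match ploidy");

  std::vector<double> y(y0.begin(), y0.end()), ynew(d);
  std::vector<double> atol(d);
  for (int j = 0; j < d; ++j) atol[j] = 1e-8 * scale[j] + 1e-12;
  Stepper st(M);

  int ntrack = track_alleles ? 1 + M.n : 1;
  std::vector<BandTracker> trk(ntrack);
  double P0 = 0.0;
  for (int i = 0; i < M.n; ++i) P0 += y[M.n + i];
  trk[0].init(P_eq, (1.0 - theta) * P_eq, P0);
  if (track_alleles)
    for (int i = 0; i < M.n; ++i)
      trk[1 + i].init(p_allele_eq[i], (1.0 - theta) * p_allele_eq[i],
                      y[M.n + i]);

  double t = 0.0, hstep = std::min(hmax, 1e-4 / delta_p);
  bool settled = false;
  M.rhs(y.data(), st.k1.data());
  long iter_guard = 0;
  while (t < horizon) {
    if (++iter_guard > 100000000L) stop("step-count guard exceeded");
    double hcur = std::min(hstep, horizon - t);
    st.step(y.data(), hcur, ynew.data());
    // scaled RMS error
    double errn = 0.0;
    for (int j = 0; j < d; ++j) {
      double sc = atol[j] + rtol * std::max(std::abs(y[j]), std::abs(ynew[j]));
      double e = st.err[j] / sc;
      errn += e * e;
    }
    errn = std::sqrt(errn / d);
    if (errn > 1.0) {  // reject, shrink
      hstep = hcur * std::max(0.2, 0.9 * std::pow(errn, -0.2));
      continue;
    }
    // accept: update trackers (k1 = f(y), k7 = f(ynew))
    double s0 = 0.0, s1 = 0.0, sd0 = 0.0, sd1 = 0.0;
    for (int i = 0; i < M.n; ++i) {
      s0 += y[M.n + i]; s1 += ynew[M.n + i];
      sd0 += st.k1[M.n + i]; sd1 += st.k7[M.n + i];
    }
    trk[0].update(t, hcur, s0, sd0, s1, sd1);
    if (track_alleles)
      for (int i = 0; i < M.n; ++i)
        trk[1 + i].update(t, hcur, y[M.n + i], st.k1[M.n + i],
                          ynew[M.n + i], st.k7[M.n + i]);
    y.swap(ynew);
    st.k1.swap(st.k7);  // FSAL
    t += hcur;
    double grow = (errn > 0) ? 0.9 * std::pow(errn, -0.2) : 5.0;
    hstep = std::min(hmax, hcur * std::min(5.0, std::max(0.2, grow)));

    double worst = -1.0;
    for (int k = 0; k < ntrack; ++k)
      worst = std::max(worst, trk[k].last_outside);
    if (t - worst >= confirm) { settled = true; break; }
  }

  NumericVector out(ntrack + 1);
  for (int k = 0; k < ntrack; ++k)
    out[k] = trk[k].ever_outside ? trk[k].last_cross : 0.0;
  out[ntrack] = settled ? 1.0 : 0.0;
  return out;
}
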