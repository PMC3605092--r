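// Exact (direct-method) stochastic simulation of the diploid birth-death
// scheme for transcription, translation and degradation under shared-pool
// Hill repression. Reactions per allele i:
//   m_i -> m_i + 1   at beta_b + beta_r / (1 + (P/K_i)^h_i)   (P = total protein)
//   m_i -> m_i - 1   at delta_m * m_i
//   p_i -> p_i + 1   at alpha * m_i
//   p_i -> p_i - 1   at delta_p * p_i
#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct SSA {
  int n;
  double bb, br, al, dm, dp;
  std::vector<double> K, h;
  std::vector<long> m, p;
  long P;  // total protein count
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  double rates[8];  // 4 per allele, n <= 2

  inline double hill(int i) const {
    if (P <= 0) return 1.0;
    if (h[i] == 1.0) return 1.0 / (1.0 + (double)P / K[i]);
    return 1.0 / (1.0 + std::pow((double)P / K[i], h[i]));
  }
  inline double total_rate() {
    double R = 0.0;
    for (int i = 0; i < n; ++i) {
      rates[4 * i]     = bb + br * hill(i);
      rates[4 * i + 1] = dm * m[i];
      rates[4 * i + 2] = al * m[i];
      rates[4 * i + 3] = dp * p[i];
      R += rates[4 * i] + rates[4 * i + 1] + rates[4 * i + 2] + rates[4 * i + 3];
    }
    return R;
  }
  inline void fire(double R) {
    double u = unif(rng) * R;
    for (int r = 0; r < 4 * n; ++r) {
      if (u < rates[r]) {
        int i = r / 4;
        switch (r % 4) {
          case 0: ++m[i]; break;
          case 1: --m[i]; break;
          case 2: ++p[i]; ++P; break;
          case 3: --p[i]; --P; break;
        }
        return;
      }
      u -= rates[r];
    }
    // floating-point slack: fire the last reaction with positive rate
    for (int r = 4 * n - 1; r >= 0; --r)
      if (rates[r] > 0) {
        int i = r / 4;
        switch (r % 4) {
          case 0: ++m[i]; break;
          case 1: --m[i]; break;
          case 2: ++p[i]; ++P; break;
          case 3: --p[i]; --P; break;
        }
        return;
      }
  }
  inline double expo(double R) {
    double u;
    do { u = unif(rng); } while (u <= 0.0);
    return -std::log(u) / R;
  }
};

SSA make_ssa(IntegerVector m0, IntegerVector p0, NumericVector K,
             NumericVector h, double bb, double br, double al, double dm,
             double dp, double seed) {
  SSA S;
  S.n = K.size();
  if (S.n > 2) stop("at most two alleles supported");
  S.bb = bb; S.br = br; S.al = al; S.dm = dm; S.dp = dp;
  S.K.assign(K.begin(), K.end());
  S.h.assign(h.begin(), h.end());
  S.m.assign(m0.begin(), m0.end());
  S.p.assign(p0.begin(), p0.end());
  S.P = 0;
  for (int i = 0; i < S.n; ++i) {
    if (S.m[i] < 0 || S.p[i] < 0) stop("negative molecule counts");
    S.P += S.p[i];
  }
  S.rng.seed((uint64_t)seed);
  return S;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".ssa_trajectory_cpp")]]
NumericMatrix ssa_trajectory_cpp(IntegerVector m0, IntegerVector p0,
                                 NumericVector K, NumericVector h,
                                 double beta_b, double beta_r, double alpha,
                                 double delta_m, double delta_p,
                                 NumericVector sample_times, double seed) {
  SSA S = make_ssa(m0, p0, K, h, beta_b, beta_r, alpha, delta_m, delta_p, seed);
  int ns = sample_times.size();
  NumericMatrix out(ns, 2 * S.n);
  double t = 0.0;
  int k = 0;
  while (k < ns) {
    double R = S.total_rate();
    double tnext = (R > 0) ? t + S.expo(R) : R_PosInf;
    while (k < ns && sample_times[k] < tnext) {
      for (int i = 0; i < S.n; ++i) {
        out(k, i) = S.m[i];
        out(k, S.n + i) = S.p[i];
      }
      ++k;
    }
    if (k >= ns) break;
    S.fire(R);
    t = tnext;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".ssa_moments_cpp")]]
NumericVector ssa_moments_cpp(IntegerVector m0, IntegerVector p0,
                              NumericVector K, NumericVector h,
                              double beta_b, double beta_r, double alpha,
                              double delta_m, double delta_p,
                              double burn_in, double window, double seed) {
  SSA S = make_ssa(m0, p0, K, h, beta_b, beta_r, alpha, delta_m, delta_p, seed);
  double t = 0.0, t_end = burn_in + window;
  // time-weighted accumulators over [burn_in, t_end]
  double sP = 0, sP2 = 0, sM = 0, sM2 = 0;
  double sp_i[2] = {0, 0}, sm_i[2] = {0, 0};
  double sP_half1 = 0;  // first half of the window, for drift check
  double half = burn_in + window / 2.0;
  while (t < t_end) {
    double R = S.total_rate();
    if (R <= 0) stop("all propensities vanished");
    double dt = S.expo(R);
    double t1 = std::min(t + dt, t_end);
    // overlap of [t, t1] with the sampling window
    double lo = std::max(t, burn_in), hi = t1;
    if (hi > lo) {
      double w = hi - lo;
      long M = 0;
      for (int i = 0; i < S.n; ++i) M += S.m[i];
      sP += w * S.P; sP2 += w * (double)S.P * S.P;
      sM += w * M;   sM2 += w * (double)M * M;
      for (int i = 0; i < S.n; ++i) { sp_i[i] += w * S.p[i]; sm_i[i] += w * S.m[i]; }
      double hi1 = std::min(hi, half);
      if (hi1 > lo) sP_half1 += (hi1 - lo) * S.P;
    }
    if (t + dt >= t_end) break;
    S.fire(R);
    t += dt;
  }
  NumericVector out(5 + 4);
  double W = window;
  out[0] = sP / W;                      // mean total protein
  out[1] = sP2 / W - (sP / W) * (sP / W);  // variance of total protein
  out[2] = sM / W;                      // mean total mRNA
  out[3] = sM2 / W - (sM / W) * (sM / W);
  out[4] = sP_half1 / (W / 2.0);        // first-half mean (drift diagnostic)
  out[5] = sm_i[0]; out[6] = sm_i[1];
  out[7] = sp_i[0] / W;
  out[8] = (S.n > 1) ? sp_i[1] / W : NA_REAL;
  out[5] /= W;
  if (S.n > 1) out[6] /= W; else out[6] = NA_REAL;
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".ssa_fpt_cpp")]]
double ssa_fpt_cpp(IntegerVector m0, IntegerVector p0, NumericVector K,
                   NumericVector h, double beta_b, double beta_r, double alpha,
                   double delta_m, double delta_p, double target,
                   double t_max, double seed) {
  SSA S = make_ssa(m0, p0, K, h, beta_b, beta_r, alpha, delta_m, delta_p, seed);
  double t = 0.0;
  if (S.P >= target) return 0.0;
  while (t < t_max) {
    double R = S.total_rate();
    if (R <= 0) return -1.0;
    t += S.expo(R);
    if (t >= t_max) return -1.0;
    S.fire(R);
    if (S.P >= target) return t;
  }
  return -1.0;
}
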