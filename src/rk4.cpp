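#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integrator for the four-state thin-filament model.
// Only (C, M1, M2) are integrated; B is recovered from conservation
// (B + C + M1 + M2 = 1 with the total site pool normalised to 1).
//
// Parameter vector layout (Ca-evaluated references precomputed in R):
//  [0] fBC0   blocked->closed reference at the working [Ca2+]
//  [1] fCB0   closed->blocked reference at the working [Ca2+]
//  [2] fCM1   closed->open reference (lowered during the slack phase)
//  [3] fM1C   open->closed reference
//  [4] kM1M2  [5] kM2M1  [6] kM2C
//  [7] u1  [8] u2  [9] z1  [10] z2  [11] v  [12] w
//  [13] alpha  [14] alpha_bar  [15] beta  [16] beta_bar

struct ModelPars {
  double fBC0, fCB0, fCM1, fM1C, kM1M2, kM2M1, kM2C;
  double cu1f, cu2f, cu1r, cu2r;   // u-coefficient combinations
  double cz1f, cz2f, cz1r, cz2r;   // z-coefficient combinations
  double evf, evr, ewf, ewr;       // exp(+/-(v-1)) - 1, exp(+/-(w-1)) - 1
  double al, alb, be, beb;
};

static ModelPars prep(const NumericVector& p) {
  ModelPars m;
  m.fBC0 = p[0]; m.fCB0 = p[1]; m.fCM1 = p[2]; m.fM1C = p[3];
  m.kM1M2 = p[4]; m.kM2M1 = p[5]; m.kM2C = p[6];
  double u1 = p[7], u2 = p[8], z1 = p[9], z2 = p[10], v = p[11], w = p[12];
  m.cu1f = 1.0 - 1.0 / u1;  m.cu2f = u2 - 1.0;
  m.cu1r = u1 - 1.0;        m.cu2r = 1.0 - 1.0 / u2;
  m.cz1f = 1.0 - 1.0 / z1;  m.cz2f = z2 - 1.0;
  m.cz1r = z1 - 1.0;        m.cz2r = 1.0 - 1.0 / z2;
  m.evf = std::exp(v - 1.0) - 1.0;  m.evr = std::exp(1.0 - v) - 1.0;
  m.ewf = std::exp(w - 1.0) - 1.0;  m.ewr = std::exp(1.0 - w) - 1.0;
  m.al = p[13]; m.alb = p[14]; m.be = p[15]; m.beb = p[16];
  return m;
}

static inline double sq(double x) { return x * x; }

static inline void rhs(const double* y, const ModelPars& m, double* dy) {
  const double C = y[0], M1 = y[1], M2 = y[2];
  const double B = 1.0 - C - M1 - M2;
  const double lamM = M1 + M2;
  const double ru_u_f = sq(1.0 - B * m.cu1f + lamM * m.cu2f);
  const double ru_u_r = sq(1.0 + B * m.cu1r - lamM * m.cu2r);
  const double ru_z_f = sq(1.0 - B * m.cz1f + lamM * m.cz2f);
  const double ru_z_r = sq(1.0 + B * m.cz1r - lamM * m.cz2r);
  const double xb_v_f = sq(1.0 + M2 * m.evf);
  const double xb_v_r = sq(1.0 + M2 * m.evr);
  const double xb_w_f = sq(1.0 + M2 * m.ewf);
  const double xb_w_r = sq(1.0 + M2 * m.ewr);
  const double kBC  = m.fBC0 * (m.al  * ru_u_f + (1.0 - m.al)  * xb_w_f);
  const double kCB  = m.fCB0 * (m.alb * ru_u_r + (1.0 - m.alb) * xb_w_r);
  const double kCM1 = m.fCM1 * (m.be  * ru_z_f + (1.0 - m.be)  * xb_v_f);
  const double kM1C = m.fM1C * (m.beb * ru_z_r + (1.0 - m.beb) * xb_v_r);
  dy[0] = kBC * B + m.kM2C * M2 + kM1C * M1 - (kCB + kCM1) * C;
  dy[1] = kCM1 * C + m.kM2M1 * M2 - (kM1C + m.kM1M2) * M1;
  dy[2] = m.kM1M2 * M1 - (m.kM2C + m.kM2M1) * M2;
}

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector y, NumericVector pars) {
  ModelPars m = prep(pars);
  double dy[3];
  rhs(REAL(y), m, dy);
  return NumericVector::create(dy[0], dy[1], dy[2]);
}

// Integrate from y0 = (C, M1, M2).
//  t_max      hard simulated-time cap (s)
//  ss_tol     if > 0, stop once max|dy/dt| < ss_tol for ss_run consecutive steps
//  record_dt  sampling interval for the returned trajectory (<= 0: endpoints only)
//  stop_m2    if >= 0, stop at the first step where M2 >= stop_m2 and append the
//             bracketing pre/post step states for interpolation in R
// [[Rcpp::export]]
List cpp_rk4(NumericVector y0, NumericVector pars, double dt, double t_max,
             double ss_tol, int ss_run, double record_dt, double stop_m2) {
  ModelPars m = prep(pars);
  double y[3] = { y0[0], y0[1], y0[2] };
  double k1[3], k2[3], k3[3], k4[3], yt[3];

  std::vector<double> ts, Cs, M1s, M2s;
  ts.reserve(1024);
  const long long n_max = (long long)std::ceil(t_max / dt);
  const long long rec_every =
    record_dt > 0.0 ? std::max(1LL, (long long)std::llround(record_dt / dt)) : 0LL;

  bool converged = false, crossed = false, unstable = false;
  int run = 0;
  double resid = NA_REAL, t = 0.0;
  double yprev[3] = { y[0], y[1], y[2] };

  ts.push_back(0.0); Cs.push_back(y[0]); M1s.push_back(y[1]); M2s.push_back(y[2]);

  long long step = 0;
  for (step = 1; step <= n_max; ++step) {
    yprev[0] = y[0]; yprev[1] = y[1]; yprev[2] = y[2];
    rhs(y, m, k1);
    for (int i = 0; i < 3; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    rhs(yt, m, k2);
    for (int i = 0; i < 3; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    rhs(yt, m, k3);
    for (int i = 0; i < 3; ++i) yt[i] = y[i] + dt * k3[i];
    rhs(yt, m, k4);
    for (int i = 0; i < 3; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    t = step * dt;

    double B = 1.0 - y[0] - y[1] - y[2];
    if (y[0] < -1e-6 || y[0] > 1.0 + 1e-6 || y[1] < -1e-6 || y[1] > 1.0 + 1e-6 ||
        y[2] < -1e-6 || y[2] > 1.0 + 1e-6 || B < -1e-6 || B > 1.0 + 1e-6 ||
        !std::isfinite(y[0]) || !std::isfinite(y[1]) || !std::isfinite(y[2])) {
      unstable = true;
      break;
    }

    if (rec_every > 0 && (step % rec_every == 0)) {
      ts.push_back(t); Cs.push_back(y[0]); M1s.push_back(y[1]); M2s.push_back(y[2]);
    }

    if (stop_m2 >= 0.0 && y[2] >= stop_m2) {
      // append the bracketing step states (previous below, current at/above)
      ts.push_back(t - dt); Cs.push_back(yprev[0]); M1s.push_back(yprev[1]); M2s.push_back(yprev[2]);
      ts.push_back(t);      Cs.push_back(y[0]);     M1s.push_back(y[1]);     M2s.push_back(y[2]);
      crossed = true;
      break;
    }

    if (ss_tol > 0.0) {
      resid = std::max(std::fabs(k1[0]), std::max(std::fabs(k1[1]), std::fabs(k1[2])));
      if (resid < ss_tol) {
        if (++run >= ss_run) { converged = true; break; }
      } else {
        run = 0;
      }
    }

    if (step % 2000000 == 0) Rcpp::checkUserInterrupt();
  }

  if (!crossed && (ts.empty() || ts.back() != t)) {
    ts.push_back(t); Cs.push_back(y[0]); M1s.push_back(y[1]); M2s.push_back(y[2]);
  }

  const R_xlen_t n = (R_xlen_t)ts.size();
  NumericMatrix states(n, 3);
  NumericVector tout(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    tout[i] = ts[i];
    states(i, 0) = Cs[i]; states(i, 1) = M1s[i]; states(i, 2) = M2s[i];
  }
  double dfin[3];
  rhs(y, m, dfin);
  double resid_fin = std::max(std::fabs(dfin[0]),
                     std::max(std::fabs(dfin[1]), std::fabs(dfin[2])));

  return List::create(
    _["t"] = tout, _["states"] = states,
    _["y_end"] = NumericVector::create(y[0], y[1], y[2]),
    _["t_end"] = t, _["converged"] = converged, _["crossed"] = crossed,
    _["unstable"] = unstable, _["resid"] = resid_fin,
    _["n_steps"] = (double)std::min(step, n_max));
}
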