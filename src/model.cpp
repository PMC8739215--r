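#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout -- must stay in sync with par_vector() in
// R/parameters.R:
//   [0..19]  c_py_py, c_py_i1, c_i1_py, c_re_re, c_tc_re, c_re_tc, c_py_tc,
//            c_py_re, c_tc_py, c_py_i2, c_tc_i1, c_tc_i2, c_ei_i1, c_ei_py,
//            c_i2_py, c_i2_i1, c_i1_i2, c_py_ei, c_i1_ei, c_tc_ei
//   [20,21]  c_Npy_py, c_Ntc_tc
//   [22..27] h_py, h_i1, h_i2, h_ei, h_tc, h_re
//   [28..33] tau_1 .. tau_6
//   [34]     epsilon
//   [35]     ei_enabled (0/1)

static inline double sig(double x, double logk) {
  // logistic transfer 1/(1 + epsilon^{-x}), overflow-safe
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-logk * x));
  double e = std::exp(logk * x);
  return e / (1.0 + e);
}

static inline void field(const double* s, const double* q, double logk,
                         double Npy, double Ntc, bool ei, double* ds) {
  const double fPY = sig(s[0], logk), fI1 = sig(s[1], logk),
               fI2 = sig(s[2], logk), fEI = sig(s[3], logk),
               fTC = sig(s[4], logk), fRE = sig(s[5], logk);
  const double ei_py = ei ? q[13] * fEI : 0.0;
  const double ei_i1 = ei ? q[12] * fEI : 0.0;
  ds[0] = q[28] * (q[22] - s[0] + q[0] * fPY - q[2] * fI1 + q[8] * fTC
                   - q[14] * fI2 + ei_py) + Npy;
  ds[1] = q[29] * (q[23] - s[1] + q[1] * fPY - q[15] * fI2 + q[10] * fTC
                   + ei_i1);
  ds[2] = q[30] * (q[24] - s[2] + q[9] * fPY - q[16] * fI1 + q[11] * fTC);
  ds[3] = ei ? q[31] * (q[25] - s[3] + q[17] * fPY - q[18] * fI1
                        + q[19] * fTC)
             : 0.0;
  ds[4] = q[32] * (q[26] - s[4] + q[6] * fPY - q[5] * fRE) + Ntc;
  ds[5] = q[33] * (q[27] - s[5] + q[7] * fPY - q[3] * fRE + q[4] * fTC);
}

static inline double cortical_mean(const double* s, bool ei) {
  return ei ? (s[0] + s[1] + s[2] + s[3]) / 4.0
            : (s[0] + s[1] + s[2]) / 3.0;
}

// [[Rcpp::export]]
NumericVector tc_field_cpp(NumericVector s, NumericVector par,
                           double Npy, double Ntc) {
  NumericVector ds(6);
  field(REAL(s), REAL(par), std::log(par[34]), Npy, Ntc, par[35] != 0.0,
        REAL(ds));
  return ds;
}

// [[Rcpp::export]]
NumericMatrix tc_jacobian_cpp(NumericVector s, NumericVector par) {
  const double* q = REAL(par);
  const double logk = std::log(q[34]);
  const bool ei = q[35] != 0.0;
  double d[6];
  for (int j = 0; j < 6; ++j) {
    double f = sig(s[j], logk);
    d[j] = logk * f * (1.0 - f);
  }
  NumericMatrix J(6, 6);
  // row PY
  J(0, 0) = q[28] * (-1.0 + q[0] * d[0]);
  J(0, 1) = q[28] * (-q[2] * d[1]);
  J(0, 2) = q[28] * (-q[14] * d[2]);
  J(0, 3) = ei ? q[28] * (q[13] * d[3]) : 0.0;
  J(0, 4) = q[28] * (q[8] * d[4]);
  // row I1
  J(1, 0) = q[29] * (q[1] * d[0]);
  J(1, 1) = -q[29];
  J(1, 2) = q[29] * (-q[15] * d[2]);
  J(1, 3) = ei ? q[29] * (q[12] * d[3]) : 0.0;
  J(1, 4) = q[29] * (q[10] * d[4]);
  // row I2
  J(2, 0) = q[30] * (q[9] * d[0]);
  J(2, 1) = q[30] * (-q[16] * d[1]);
  J(2, 2) = -q[30];
  J(2, 4) = q[30] * (q[11] * d[4]);
  // row EI (frozen when the population is ablated)
  if (ei) {
    J(3, 0) = q[31] * (q[17] * d[0]);
    J(3, 1) = q[31] * (-q[18] * d[1]);
    J(3, 3) = -q[31];
    J(3, 4) = q[31] * (q[19] * d[4]);
  }
  // row TC
  J(4, 0) = q[32] * (q[6] * d[0]);
  J(4, 4) = -q[32];
  J(4, 5) = q[32] * (-q[5] * d[5]);
  // row RE
  J(5, 0) = q[33] * (q[7] * d[0]);
  J(5, 4) = q[33] * (q[4] * d[4]);
  J(5, 5) = q[33] * (-1.0 - q[3] * d[5]);
  return J;
}

// Classic fixed-step RK4 with time-dependent sinusoidal drives.
// drive = (B_Npy, a_py, fpy, B_Ntc, a_tc, ftc); absolute time t0 + k*dt is
// used inside the sines so chained runs keep drive phase continuity.
// Returns trajectory, cortical-mean output and the step index at which the
// divergence guard (|state| > guard) tripped, or -1.
// [[Rcpp::export]]
List tc_rk4_cpp(NumericVector s0, double t0, int n_steps, double dt,
                NumericVector par, NumericVector drive,
                double guard = 1e6) {
  const double* q = REAL(par);
  const double logk = std::log(q[34]);
  const bool ei = q[35] != 0.0;
  const double gNpy = q[20], gNtc = q[21];
  const double B_Npy = drive[0], a_py = drive[1], fpy = drive[2];
  const double B_Ntc = drive[3], a_tc = drive[4], ftc = drive[5];
  const double twopi = 2.0 * M_PI;

  NumericMatrix states(n_steps + 1, 6);
  NumericVector output(n_steps + 1);
  double s[6], k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int j = 0; j < 6; ++j) { s[j] = s0[j]; states(0, j) = s[j]; }
  output[0] = cortical_mean(s, ei);
  int diverged = -1;

  for (int k = 0; k < n_steps; ++k) {
    const double t = t0 + k * dt;
    const double th = t + 0.5 * dt, t1 = t + dt;
    const double Npy0 = gNpy * (B_Npy + a_py * std::sin(twopi * fpy * t));
    const double Npyh = gNpy * (B_Npy + a_py * std::sin(twopi * fpy * th));
    const double Npy1 = gNpy * (B_Npy + a_py * std::sin(twopi * fpy * t1));
    const double Ntc0 = gNtc * (B_Ntc + a_tc * std::sin(twopi * ftc * t));
    const double Ntch = gNtc * (B_Ntc + a_tc * std::sin(twopi * ftc * th));
    const double Ntc1 = gNtc * (B_Ntc + a_tc * std::sin(twopi * ftc * t1));

    field(s, q, logk, Npy0, Ntc0, ei, k1);
    for (int j = 0; j < 6; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    field(tmp, q, logk, Npyh, Ntch, ei, k2);
    for (int j = 0; j < 6; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    field(tmp, q, logk, Npyh, Ntch, ei, k3);
    for (int j = 0; j < 6; ++j) tmp[j] = s[j] + dt * k3[j];
    field(tmp, q, logk, Npy1, Ntc1, ei, k4);

    bool bad = false;
    for (int j = 0; j < 6; ++j) {
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(s[j]) || std::fabs(s[j]) > guard) bad = true;
      states(k + 1, j) = s[j];
    }
    output[k + 1] = cortical_mean(s, ei);
    if (bad) { diverged = k + 1; break; }
  }
  return List::create(_["states"] = states, _["output"] = output,
                      _["diverged"] = diverged);
}
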