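// Compiled core: the two ventricular cell models (modified Pandit neonatal
// mouse; reduced ten Tusscher-Panfilov human), their paced / clamped
// integrators, and the closed-loop cell-type transforming clamp (CTC).
//
// Conventions (package-wide):
//   * all currents are capacitance-normalized (pA/pF) and outward-positive;
//   * the membrane equation is dV/dt = -(i_ion + i_applied)  [mV/ms];
//   * V is advanced by forward Euler; Hodgkin-Huxley gates by the exact
//     exponential (Rush-Larsen) update, which is required for stability at
//     the 0.1 ms mouse-model step (the Na activation gate has tau << dt
//     around the resting potential).
//
// State layouts (fixed; mirrored in R/model-params.R):
//   mouse (14): V m h j d f11 f12 cainact r s sslow rss sss y
//   human (12): V m h j d f fca r s xr1 xr2 xs

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// exp() with an opt-in Schraudolph-style fast approximation (the rig used
// fast transcendental approximations for real-time speed; default is exact)
// ---------------------------------------------------------------------------
static bool g_fast_exp = false;

static inline double fast_exp_approx(double x) {
  // range reduction: x = k ln2 + r, |r| <= ln2/2; exp(r) by a degree-6
  // polynomial; rebuild with ldexp. ~1e-9 relative error. (The classic
  // Schraudolph bit-trick is ~3% off, which the stiff gate ODEs cannot
  // tolerate: it qualitatively changes the AP.)
  double k = std::nearbyint(x * 1.4426950408889634); // x / ln 2
  double r = x - k * 0.6931471805599453;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6.0 + r * (1.0 / 24.0 +
             r * (1.0 / 120.0 + r * (1.0 / 720.0))))));
  return std::ldexp(p, (int)k);
}

static inline double EXP(double x) {
  if (!g_fast_exp) return std::exp(x);
  if (x < -700.0) return 0.0;
  if (x > 700.0) return std::exp(x);
  return fast_exp_approx(x);
}

// [[Rcpp::export]]
void cpp_set_fast_exp(bool on) { g_fast_exp = on; }

// [[Rcpp::export]]
bool cpp_get_fast_exp() { return g_fast_exp; }

// Rush-Larsen: advance gate x toward xinf with time constant tau (ms)
static inline double rl(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * EXP(-dt / tau);
}

// ===========================================================================
// Modified Pandit neonatal mouse ventricular model
// ===========================================================================

#define MOUSE_NS 14
// parameter order (mirrored in R):
// 0 gNa 1 gCaL 2 gt 3 gKslow 4 gss 5 gK1 6 gf 7 gBNa 8 gBCa 9 gBK
// 10 iNaKmax 11 kNaCa 12 iCaPmax 13 Ko 14 Nao 15 Cao 16 Nai 17 Ki 18 Cai
// 19 Cm_pF
#define MOUSE_NP 20

static const double MOUSE_RTF = 8314.5 * 295.0 / 96487.0; // mV, T = 295 K

// component order for the mouse current decomposition
// 0 iNa 1 iCaL 2 it 3 iKslow 4 iss 5 if 6 iK1 7 iBNa 8 iBCa 9 iBK
// 10 iNaK 11 iNaCa 12 iCaP 13 total
#define MOUSE_NC 14

static void mouse_currents(double V, const double* y, const double* p,
                           double* out) {
  const double Ko = p[13], Nao = p[14], Cao = p[15];
  const double Nai = p[16], Ki = p[17], Cai = p[18];
  const double ENa = MOUSE_RTF * std::log(Nao / Nai);
  const double EK  = MOUSE_RTF * std::log(Ko / Ki);
  const double ECa = 0.5 * MOUSE_RTF * std::log(Cao / Cai);

  // whole-cell currents in nA (conductances in uS), normalized at the end
  const double m = y[1], h = y[2], j = y[3];
  const double d = y[4], f11 = y[5], f12 = y[6], ca = y[7];
  const double r = y[8], s = y[9], sslow = y[10];
  const double rss = y[11], sss = y[12], yf = y[13];

  const double iNa  = p[0] * m * m * m * h * j * (V - ENa);
  const double iCaL = p[1] * d * ((0.9 + ca / 10.0) * f11 +
                                  (0.1 - ca / 10.0) * f12) * (V - 65.0);
  // Pandit's Ca-independent transient outward current split into its fast
  // (g_t, gate s) and slowly inactivating (g_Kslow, gate s_slow) components
  const double it     = p[2] * 0.886 * r * s * (V - EK);
  const double iKslow = p[3] * 0.114 * r * sslow * (V - EK);
  const double iss    = p[4] * rss * sss * (V - EK);
  const double if_    = p[6] * yf * (0.2 * (V - ENa) + 0.8 * (V - EK));
  const double dvk = V - EK - 76.77;
  const double iK1 =
    (0.048 / (EXP((V + 37.0) / 25.0) + EXP(-(V + 37.0) / 25.0)) + 0.01) *
      0.001 / (1.0 + EXP(-dvk / 17.0)) +
    p[5] * (V - EK - 1.73) /
      ((1.0 + EXP(1.613 * (V - EK - 1.73) / MOUSE_RTF)) *
       (1.0 + EXP(-(Ko - 0.9988) / 0.124)));
  const double iBNa = p[7] * (V - ENa);
  const double iBCa = p[8] * (V - ECa);
  const double iBK  = p[9] * (V - EK);
  const double sigma = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  const double fNaK = 1.0 / (1.0 + 0.1245 * EXP(-0.1 * V / MOUSE_RTF) +
                             0.0365 * sigma * EXP(-V / MOUSE_RTF));
  const double iNaK = p[10] * fNaK * (Ko / (Ko + 1.5)) /
                      (1.0 + std::pow(10.0 / Nai, 1.5));
  const double na3 = Nai * Nai * Nai, nao3 = Nao * Nao * Nao;
  const double iNaCa = p[11] *
    (na3 * Cao * EXP(0.03743 * 0.5 * V) -
     nao3 * Cai * EXP(-0.03743 * 0.5 * V)) /
    (1.0 + 0.0001 * (na3 * Cao + nao3 * Cai));
  const double iCaP = p[12] * Cai / (Cai + 0.0004);

  const double k = 1000.0 / p[19]; // nA -> pA/pF
  out[0] = iNa * k;    out[1] = iCaL * k;  out[2] = it * k;
  out[3] = iKslow * k; out[4] = iss * k;   out[5] = if_ * k;
  out[6] = iK1 * k;    out[7] = iBNa * k;  out[8] = iBCa * k;
  out[9] = iBK * k;    out[10] = iNaK * k; out[11] = iNaCa * k;
  out[12] = iCaP * k;
  double tot = 0.0;
  for (int i = 0; i < 13; ++i) tot += out[i];
  out[13] = tot;
}

static void mouse_gates(double V, double* y, const double* p, double dt) {
  // I_Na gates
  double dv = V + 47.13;
  double a_m = (std::fabs(dv) < 1e-6) ? 3.2
             : 0.32 * dv / (1.0 - EXP(-0.1 * dv));
  double tau_m = 1.36 / (a_m + 0.08 * EXP(-V / 11.0));
  double m_inf = 1.0 / (1.0 + EXP(-(V + 45.0) / 6.5));
  double h_inf = 1.0 / (1.0 + EXP((V + 76.1) / 6.07));
  double tau_h, tau_j;
  if (V >= -40.0) {
    tau_h = 0.4537 * (1.0 + EXP(-(V + 10.66) / 11.1));
    tau_j = 11.63 * (1.0 + EXP(-0.1 * (V + 32.0))) / EXP(-2.535e-7 * V);
  } else {
    tau_h = 3.49 / (0.135 * EXP(-(V + 80.0) / 6.8) +
                    3.56 * EXP(0.079 * V) + 310000.0 * EXP(0.35 * V));
    tau_j = 3.49 /
      ((V + 37.78) / (1.0 + EXP(0.311 * (V + 79.23))) *
         (-127140.0 * EXP(0.2444 * V) - 3.474e-5 * EXP(-0.04391 * V)) +
       0.1212 * EXP(-0.01052 * V) / (1.0 + EXP(-0.1378 * (V + 40.14))));
  }
  // I_CaL gates
  double d_inf = 1.0 / (1.0 + EXP(-(V + 15.3) / 5.0));
  double tau_d = 3.05 * EXP(-0.0045 * (V + 7.0) * (V + 7.0)) +
                 1.05 * EXP(-0.002 * (V - 18.0) * (V - 18.0)) + 0.25;
  double f_inf = 1.0 / (1.0 + EXP((V + 26.7) / 5.4));
  double v45 = (V + 45.0) / 12.0, v47 = (V + 47.0) / 12.0;
  double tau_f11 = 105.0 * EXP(-v45 * v45) +
                   40.0 / (1.0 + EXP((-V + 25.0) / 25.0)) +
                   15.0 / (1.0 + EXP((V + 75.0) / 25.0)) + 1.7;
  double tau_f12 = 41.0 * EXP(-v47 * v47) +
                   80.0 / (1.0 + EXP(-(V + 55.0) / 5.0)) +
                   15.0 / (1.0 + EXP((V + 75.0) / 25.0)) + 1.7;
  double ca_inf = 1.0 / (1.0 + p[18] / 0.01); // fixed [Ca2+]i -> constant
  // K+ current gates
  double r_inf = 1.0 / (1.0 + EXP(-(V + 10.6) / 11.42));
  double denom_r = 45.16 * EXP(0.03577 * (V + 50.0)) +
                   98.9 * EXP(-0.1 * (V + 38.0));
  double tau_r = 1000.0 / denom_r;
  double s_inf = 1.0 / (1.0 + EXP((V + 45.3) / 6.8841));
  double v70a = (V + 70.0) / 15.0, v70b = (V + 70.0) / 30.0;
  double tau_s = 350.0 * EXP(-v70a * v70a) + 35.0;
  double tau_sslow = 3700.0 * EXP(-v70b * v70b) + 35.0;
  double rss_inf = 1.0 / (1.0 + EXP(-(V + 11.5) / 11.82));
  double tau_rss = 10000.0 / denom_r;
  double sss_inf = 1.0 / (1.0 + EXP((V + 87.5) / 10.3));
  double tau_sss = 2100.0;
  // I_f gate
  double y_inf = 1.0 / (1.0 + EXP((V + 138.6) / 10.48));
  double tau_y = 1000.0 / (0.11885 * EXP((V + 80.0) / 28.37) +
                           0.56236 * EXP(-(V + 80.0) / 14.19));

  y[1] = rl(y[1], m_inf, tau_m, dt);
  y[2] = rl(y[2], h_inf, tau_h, dt);
  y[3] = rl(y[3], h_inf, tau_j, dt);
  y[4] = rl(y[4], d_inf, tau_d, dt);
  y[5] = rl(y[5], f_inf, tau_f11, dt);
  y[6] = rl(y[6], f_inf, tau_f12, dt);
  y[7] = rl(y[7], ca_inf, 9.0, dt);
  y[8] = rl(y[8], r_inf, tau_r, dt);
  y[9] = rl(y[9], s_inf, tau_s, dt);
  y[10] = rl(y[10], s_inf, tau_sslow, dt);
  y[11] = rl(y[11], rss_inf, tau_rss, dt);
  y[12] = rl(y[12], sss_inf, tau_sss, dt);
  y[13] = rl(y[13], y_inf, tau_y, dt);
}

// ===========================================================================
// Reduced ten Tusscher-Panfilov human ventricular model (epicardial;
// intracellular concentrations fixed at diastolic values)
// ===========================================================================

#define HUMAN_NS 12
// parameter order:
// 0 gNa 1 gCaL 2 gto 3 gKr 4 gKs 5 gK1 6 kNaCa 7 pNaK 8 gpCa 9 gpK
// 10 gbNa 11 gbCa 12 Ko 13 Nao 14 Cao 15 Nai 16 Ki 17 Cai 18 Cm_pF
// 19 CaLdrive (effective submembrane [Ca2+] in the L-type driving force;
//    part of the fixed-concentration reduction)
#define HUMAN_NP 20

static const double HUMAN_F = 96485.3415;
static const double HUMAN_RTF = 8314.472 * 310.0 / HUMAN_F; // mV

// component order:
// 0 iNa 1 iCaL 2 ito 3 iKr 4 iKs 5 iK1 6 iNaCa 7 iNaK 8 ipCa 9 ipK
// 10 ibNa 11 ibCa 12 total
#define HUMAN_NC 13

static void human_currents(double V, const double* y, const double* p,
                           double* out) {
  const double Ko = p[12], Nao = p[13], Cao = p[14];
  const double Nai = p[15], Ki = p[16], Cai = p[17];
  const double ENa = HUMAN_RTF * std::log(Nao / Nai);
  const double EK  = HUMAN_RTF * std::log(Ko / Ki);
  const double ECa = 0.5 * HUMAN_RTF * std::log(Cao / Cai);
  const double EKs = HUMAN_RTF *
    std::log((Ko + 0.03 * Nao) / (Ki + 0.03 * Nai));

  const double m = y[1], h = y[2], j = y[3];
  const double d = y[4], f = y[5], fca = y[6];
  const double r = y[7], s = y[8];
  const double xr1 = y[9], xr2 = y[10], xs = y[11];

  const double iNa = p[0] * m * m * m * h * j * (V - ENa);
  double iCaL;
  {
    const double casub = p[19]; // effective submembrane Ca2+ (mM)
    const double z = 2.0 * V / HUMAN_RTF;
    double galv; // 4VF^2/RT * (0.25 Ca_sub e^z - Cao) / (e^z - 1)
    if (std::fabs(z) < 1e-5) {
      galv = 2.0 * HUMAN_F * (0.25 * casub - Cao); // limit V -> 0
    } else {
      const double ez = EXP(z);
      galv = 4.0 * V * (HUMAN_F / HUMAN_RTF) * (0.25 * casub * ez - Cao) /
             (ez - 1.0);
    }
    iCaL = p[1] * d * f * fca * galv;
  }
  const double ito = p[2] * r * s * (V - EK);
  const double sqko = std::sqrt(Ko / 5.4);
  const double iKr = p[3] * sqko * xr1 * xr2 * (V - EK);
  const double iKs = p[4] * xs * xs * (V - EKs);
  const double vk = V - EK;
  const double aK1 = 0.1 / (1.0 + EXP(0.06 * (vk - 200.0)));
  const double bK1 = (3.0 * EXP(0.0002 * (vk + 100.0)) +
                      EXP(0.1 * (vk - 10.0))) /
                     (1.0 + EXP(-0.5 * vk));
  const double iK1 = p[5] * (aK1 / (aK1 + bK1)) * sqko * vk;
  const double na3 = Nai * Nai * Nai, nao3 = Nao * Nao * Nao;
  const double kmna3 = 87.5 * 87.5 * 87.5;
  const double e1 = EXP(0.35 * V / HUMAN_RTF);
  const double e2 = EXP(-0.65 * V / HUMAN_RTF);
  const double iNaCa = p[6] * (e1 * na3 * Cao - e2 * nao3 * Cai * 2.5) /
    ((kmna3 + nao3) * (1.38 + Cao) * (1.0 + 0.1 * e2));
  const double iNaK = p[7] * Ko * Nai /
    ((Ko + 1.0) * (Nai + 40.0) *
     (1.0 + 0.1245 * EXP(-0.1 * V / HUMAN_RTF) +
      0.0353 * EXP(-V / HUMAN_RTF)));
  const double ipCa = p[8] * Cai / (0.0005 + Cai);
  const double ipK = p[9] * vk / (1.0 + EXP((25.0 - V) / 5.98));
  const double ibNa = p[10] * (V - ENa);
  const double ibCa = p[11] * (V - ECa);

  out[0] = iNa;  out[1] = iCaL;  out[2] = ito;  out[3] = iKr;
  out[4] = iKs;  out[5] = iK1;   out[6] = iNaCa; out[7] = iNaK;
  out[8] = ipCa; out[9] = ipK;   out[10] = ibNa; out[11] = ibCa;
  double tot = 0.0;
  for (int i = 0; i < 12; ++i) tot += out[i];
  out[12] = tot;
}

static void human_gates(double V, double* y, const double* p, double dt) {
  const double Cai = p[17];
  double tmp;
  // m
  tmp = 1.0 + EXP((-56.86 - V) / 9.03);
  double m_inf = 1.0 / (tmp * tmp);
  double a_m = 1.0 / (1.0 + EXP((-60.0 - V) / 5.0));
  double b_m = 0.1 / (1.0 + EXP((V + 35.0) / 5.0)) +
               0.1 / (1.0 + EXP((V - 50.0) / 200.0));
  double tau_m = a_m * b_m;
  // h, j
  tmp = 1.0 + EXP((V + 71.55) / 7.43);
  double h_inf = 1.0 / (tmp * tmp);
  double tau_h, tau_j;
  if (V >= -40.0) {
    tau_h = 1.0 / (0.77 / (0.13 * (1.0 + EXP(-(V + 10.66) / 11.1))));
    tau_j = 1.0 / (0.6 * EXP(0.057 * V) / (1.0 + EXP(-0.1 * (V + 32.0))));
  } else {
    double a_h = 0.057 * EXP(-(V + 80.0) / 6.8);
    double b_h = 2.7 * EXP(0.079 * V) + 310000.0 * EXP(0.3485 * V);
    tau_h = 1.0 / (a_h + b_h);
    double a_j = (-25428.0 * EXP(0.2444 * V) - 6.948e-6 * EXP(-0.04391 * V)) *
                 (V + 37.78) / (1.0 + EXP(0.311 * (V + 79.23)));
    double b_j = 0.02424 * EXP(-0.01052 * V) /
                 (1.0 + EXP(-0.1378 * (V + 40.14)));
    tau_j = 1.0 / (a_j + b_j);
  }
  // d
  double d_inf = 1.0 / (1.0 + EXP((-5.0 - V) / 7.5));
  double a_d = 1.4 / (1.0 + EXP((-35.0 - V) / 13.0)) + 0.25;
  double b_d = 1.4 / (1.0 + EXP((V + 5.0) / 5.0));
  double g_d = 1.0 / (1.0 + EXP((50.0 - V) / 20.0));
  double tau_d = a_d * b_d + g_d;
  // f
  double f_inf = 1.0 / (1.0 + EXP((V + 20.0) / 7.0));
  double tau_f = 1125.0 * EXP(-(V + 27.0) * (V + 27.0) / 240.0) + 80.0 +
                 165.0 / (1.0 + EXP((25.0 - V) / 10.0));
  // fCa (constant with fixed Cai; keep the published gate + gating rule)
  double c8 = std::pow(Cai / 0.000325, 8.0);
  double a_fca = 1.0 / (1.0 + c8);
  double b_fca = 0.1 / (1.0 + EXP((Cai - 0.0005) / 0.0001));
  double g_fca = 0.2 / (1.0 + EXP((Cai - 0.00075) / 0.0008));
  double fca_inf = (a_fca + b_fca + g_fca + 0.23) / 1.46;
  // r, s (epicardial)
  double r_inf = 1.0 / (1.0 + EXP((20.0 - V) / 6.0));
  double tau_r = 9.5 * EXP(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  double s_inf = 1.0 / (1.0 + EXP((V + 20.0) / 5.0));
  double tau_s = 85.0 * EXP(-(V + 45.0) * (V + 45.0) / 320.0) +
                 5.0 / (1.0 + EXP((V - 20.0) / 5.0)) + 3.0;
  // xr1, xr2
  double xr1_inf = 1.0 / (1.0 + EXP((-26.0 - V) / 7.0));
  double a_xr1 = 450.0 / (1.0 + EXP((-45.0 - V) / 10.0));
  double b_xr1 = 6.0 / (1.0 + EXP((V + 30.0) / 11.5));
  double tau_xr1 = a_xr1 * b_xr1;
  double xr2_inf = 1.0 / (1.0 + EXP((V + 88.0) / 24.0));
  double a_xr2 = 3.0 / (1.0 + EXP((-60.0 - V) / 20.0));
  double b_xr2 = 1.12 / (1.0 + EXP((V - 60.0) / 20.0));
  double tau_xr2 = a_xr2 * b_xr2;
  // xs
  double xs_inf = 1.0 / (1.0 + EXP((-5.0 - V) / 14.0));
  double a_xs = 1100.0 / std::sqrt(1.0 + EXP((-10.0 - V) / 6.0));
  double b_xs = 1.0 / (1.0 + EXP((V - 60.0) / 20.0));
  double tau_xs = a_xs * b_xs;

  y[1] = rl(y[1], m_inf, tau_m, dt);
  y[2] = rl(y[2], h_inf, tau_h, dt);
  y[3] = rl(y[3], h_inf, tau_j, dt);
  y[4] = rl(y[4], d_inf, tau_d, dt);
  y[5] = rl(y[5], f_inf, tau_f, dt);
  // published rule: fCa may not recover while depolarized
  if (!(fca_inf > y[6] && V > -60.0)) y[6] = rl(y[6], fca_inf, 2.0, dt);
  y[7] = rl(y[7], r_inf, tau_r, dt);
  y[8] = rl(y[8], s_inf, tau_s, dt);
  y[9] = rl(y[9], xr1_inf, tau_xr1, dt);
  y[10] = rl(y[10], xr2_inf, tau_xr2, dt);
  y[11] = rl(y[11], xs_inf, tau_xs, dt);
}

// ===========================================================================
// dispatch helpers (kind: 0 = mouse, 1 = human)
// ===========================================================================

static inline int n_state(int kind) { return kind == 0 ? MOUSE_NS : HUMAN_NS; }
static inline int n_comp(int kind)  { return kind == 0 ? MOUSE_NC : HUMAN_NC; }

static inline double total_current(int kind, double V, const double* y,
                                   const double* p, double* scratch) {
  if (kind == 0) { mouse_currents(V, y, p, scratch); return scratch[13]; }
  human_currents(V, y, p, scratch);
  return scratch[12];
}

static inline void gate_update(int kind, double V, double* y, const double* p,
                               double dt) {
  if (kind == 0) mouse_gates(V, y, p, dt);
  else human_gates(V, y, p, dt);
}

static void check_finite(const double* y, int n, double t) {
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i]))
      stop("non-finite model state (component %d) at t = %.4f ms", i + 1, t);
}

// ---------------------------------------------------------------------------
// exported single-step / current primitives
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_currents(int kind, NumericVector state, NumericVector params,
                           double V) {
  std::vector<double> out(n_comp(kind));
  if (kind == 0) mouse_currents(V, REAL(state), REAL(params), out.data());
  else human_currents(V, REAL(state), REAL(params), out.data());
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector cpp_step_clamped(int kind, NumericVector state,
                               NumericVector params, double V, double dt) {
  NumericVector out = clone(state);
  gate_update(kind, V, REAL(out), REAL(params), dt);
  out[0] = V;
  check_finite(REAL(out), n_state(kind), NA_REAL);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_step_free(int kind, NumericVector state,
                            NumericVector params, double i_applied, double dt) {
  NumericVector out = clone(state);
  double scratch[MOUSE_NC];
  double V = out[0];
  double i_ion = total_current(kind, V, REAL(out), REAL(params), scratch);
  gate_update(kind, V, REAL(out), REAL(params), dt);
  out[0] = V - dt * (i_ion + i_applied);
  check_finite(REAL(out), n_state(kind), NA_REAL);
  return out;
}

// ---------------------------------------------------------------------------
// paced free-running simulation
// ---------------------------------------------------------------------------

// Returns V sampled at t = 0, dt, ..., n_steps*dt (n_steps+1 samples).
// Stimulus: depolarizing amplitude `amp` (pA/pF) during [onset, onset+dur).
// [[Rcpp::export]]
List cpp_simulate(int kind, NumericVector state, NumericVector params,
                  double dt, int n_steps, NumericVector stim_onsets,
                  double stim_dur, double stim_amp, bool record_states) {
  int ns = n_state(kind);
  std::vector<double> y(REAL(state), REAL(state) + ns);
  NumericVector v(n_steps + 1);
  NumericMatrix states;
  if (record_states) states = NumericMatrix(n_steps + 1, ns);
  double scratch[MOUSE_NC];
  int n_on = stim_onsets.size();
  int next_on = 0;
  double stim_until = -1.0;
  v[0] = y[0];
  if (record_states) for (int s = 0; s < ns; ++s) states(0, s) = y[s];
  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    // stimulus window bookkeeping (half-step tolerance on onset times)
    if (next_on < n_on && t >= stim_onsets[next_on] - 0.5 * dt) {
      stim_until = stim_onsets[next_on] + stim_dur - 0.5 * dt;
      ++next_on;
    }
    double i_app = (t < stim_until) ? -stim_amp : 0.0;
    double V = y[0];
    double i_ion = total_current(kind, V, y.data(), REAL(params), scratch);
    gate_update(kind, V, y.data(), REAL(params), dt);
    y[0] = V - dt * (i_ion + i_app);
    if (!R_finite(y[0]))
      stop("numerical blow-up at t = %.4f ms", t + dt);
    v[k + 1] = y[0];
    if (record_states) for (int s = 0; s < ns; ++s) states(k + 1, s) = y[s];
  }
  check_finite(y.data(), ns, n_steps * dt);
  List out = List::create(_["v"] = v, _["final_state"] = wrap(y));
  if (record_states) out["states"] = states;
  return out;
}

// ---------------------------------------------------------------------------
// closed-loop cell-type transforming clamp
// ---------------------------------------------------------------------------

// Target and canceling models are stepped at the loop step `dt`; the
// recipient is sub-stepped `n_sub` times at dt/n_sub with V held (multirate
// scheme reconciling the two published integration steps).
//
// Record columns: t, v_target, i_cancel, i_recipient, i_diff, i_seal,
// i_inject (all currents pA/pF, outward-positive, normalized to the target
// capacitance where they enter the target membrane equation).
// [[Rcpp::export]]
NumericMatrix cpp_run_ctc(int kind_target, NumericVector target_state,
                          NumericVector target_params,
                          int kind_cancel, NumericVector cancel_state,
                          NumericVector cancel_params,
                          int kind_recipient, NumericVector recipient_state,
                          NumericVector recipient_params,
                          double dt, int n_sub, int n_steps,
                          NumericVector stim_onsets, double stim_dur,
                          double stim_amp,
                          double r_seal_GOhm, double c_target_pF,
                          double ljp_mV) {
  int ns_t = n_state(kind_target);
  int ns_c = n_state(kind_cancel);
  int ns_r = n_state(kind_recipient);
  std::vector<double> yt(REAL(target_state), REAL(target_state) + ns_t);
  std::vector<double> yc(REAL(cancel_state), REAL(cancel_state) + ns_c);
  std::vector<double> yr(REAL(recipient_state), REAL(recipient_state) + ns_r);
  double scratch[MOUSE_NC];
  const double dt_sub = dt / n_sub;
  const bool has_seal = R_finite(r_seal_GOhm);
  NumericMatrix rec(n_steps, 7);
  int n_on = stim_onsets.size();
  int next_on = 0;
  double stim_until = -1.0;

  for (int k = 0; k < n_steps; ++k) {
    double t = k * dt;
    if (next_on < n_on && t >= stim_onsets[next_on] - 0.5 * dt) {
      stim_until = stim_onsets[next_on] + stim_dur - 0.5 * dt;
      ++next_on;
    }
    double i_stim = (t < stim_until) ? -stim_amp : 0.0;

    // step 1: measure target voltage, correct for LJP
    double Vm = yt[0] + ljp_mV;

    // steps 2-3: model currents at the measured voltage (normalized; the
    // capacitance ratios K_c, K_r cancel exactly in normalized units)
    double i_cancel = total_current(kind_cancel, Vm, yc.data(),
                                    REAL(cancel_params), scratch);
    double i_recip = total_current(kind_recipient, Vm, yr.data(),
                                   REAL(recipient_params), scratch);

    // advance the clamped models at the measured voltage
    gate_update(kind_cancel, Vm, yc.data(), REAL(cancel_params), dt);
    yc[0] = Vm;
    for (int s = 0; s < n_sub; ++s)
      gate_update(kind_recipient, Vm, yr.data(), REAL(recipient_params),
                  dt_sub);
    yr[0] = Vm;

    // step 4: difference current
    double i_diff = i_recip - i_cancel;

    // step 5: physical seal leak on the (raw) target voltage and its
    // compensation; stimulus delivered through the injection path
    double i_seal = has_seal ? (yt[0] / r_seal_GOhm) * (1000.0 / c_target_pF)
                             : 0.0; // mV/GOhm = pA, then normalize
    double i_inject = i_diff + i_stim - i_seal;

    rec(k, 0) = t;      rec(k, 1) = yt[0];  rec(k, 2) = i_cancel;
    rec(k, 3) = i_recip; rec(k, 4) = i_diff; rec(k, 5) = i_seal;
    rec(k, 6) = i_inject;

    // step 6: inject into the free-running target (which also carries the
    // physical seal leak when R_seal is finite)
    double V = yt[0];
    double i_ion = total_current(kind_target, V, yt.data(),
                                 REAL(target_params), scratch);
    gate_update(kind_target, V, yt.data(), REAL(target_params), dt);
    yt[0] = V - dt * (i_ion + i_seal + i_inject);
    if (!R_finite(yt[0]))
      stop("CTC numerical blow-up at t = %.4f ms", t + dt);
  }
  return rec;
}
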