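// Courtemanche-Ramirez-Nattel (1998) human atrial myocyte model and the
// operator-split monodomain stepper built on it.
//
// State layout (21 variables, in this order everywhere):
//   0 V (mV), 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 f_Ca, 13 u, 14 v, 15 w,
//   16 Na_i, 17 K_i, 18 Ca_i, 19 Ca_up, 20 Ca_rel (mM)
//
// Channel scaling factor layout (6): f_K1, f_NCX, f_Na, f_to, f_CaL, f_Kur.
// Constants follow the curated CellML encoding of the original publication.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#define N_STATE 21
#define N_GATE 15 // state indices 1..15

// physical constants
static const double Rgas = 8.3143;    // J/(mol K)
static const double Temp = 310.0;     // K
static const double Frdy = 96.4867;   // C/mmol
static const double Cm = 100.0;       // pF

// cell geometry (um^3)
static const double V_cell = 20100.0;
static const double V_i = 13668.0;
static const double V_up = 1109.52;
static const double V_rel = 96.48;

// external concentrations (mM)
static const double K_o = 5.4;
static const double Na_o = 140.0;
static const double Ca_o = 1.8;

// maximal conductances (nS/pF) and pump/exchanger constants
static const double g_Na = 7.8;
static const double g_K1 = 0.09;
static const double g_to = 0.1652;
static const double g_Kr = 0.029411765;
static const double g_Ks = 0.12941176;
static const double g_Ca_L = 0.12375;
static const double g_B_Ca = 0.001131;
static const double g_B_Na = 0.0006744375;
static const double i_NaK_max = 0.59933874; // pA/pF
static const double Km_Na_i = 10.0;
static const double Km_K_o = 1.5;
static const double i_CaP_max = 0.275;      // pA/pF
static const double I_NaCa_max = 1600.0;    // pA/pF
static const double K_mNa = 87.5;
static const double K_mCa = 1.38;
static const double K_sat = 0.1;
static const double gamma_ncx = 0.35;

// SR calcium handling
static const double K_rel = 30.0;     // 1/ms
static const double I_up_max = 0.005; // mM/ms
static const double K_up = 0.00092;   // mM
static const double Ca_up_max = 15.0; // mM
static const double tau_tr = 180.0;   // ms
static const double tau_f_Ca = 2.0;   // ms
static const double tau_u = 8.0;      // ms

// buffers
static const double CMDN_max = 0.05;
static const double TRPN_max = 0.07;
static const double CSQN_max = 10.0;
static const double Km_CMDN = 0.00238;
static const double Km_TRPN = 0.0005;
static const double Km_CSQN = 0.8;

static const double K_Q10 = 3.0;

// Evaluate currents, gate targets (inf, tau) and concentration rates at one
// state. i_stim in pA (negative = depolarizing). Returns dV/dt in mV/ms.
// cur (optional, length 12): named current outputs in pA.
static inline double crn_core(const double* y, const double* f, double i_stim,
                              double* inf, double* tau, double* conc_dot,
                              double* cur) {
  const double V = y[0];
  const double m = y[1], h = y[2], j = y[3];
  const double oa = y[4], oi = y[5], ua = y[6], ui = y[7];
  const double xr = y[8], xs = y[9];
  const double d = y[10], fg = y[11], f_Ca = y[12];
  const double u = y[13], v = y[14], w = y[15];
  const double Na_i = y[16], K_i = y[17], Ca_i = y[18];
  const double Ca_up = y[19], Ca_rel = y[20];

  const double RTF = Rgas * Temp / Frdy;
  const double E_Na = RTF * std::log(Na_o / Na_i);
  const double E_K = RTF * std::log(K_o / K_i);
  const double E_Ca = 0.5 * RTF * std::log(Ca_o / Ca_i);

  // --- membrane currents (pA), with channel scaling factors applied ---
  const double i_Na = f[2] * Cm * g_Na * m * m * m * h * j * (V - E_Na);
  const double i_K1 = f[0] * Cm * g_K1 * (V - E_K) /
                      (1.0 + std::exp(0.07 * (V + 80.0)));
  const double i_to = f[3] * Cm * g_to * oa * oa * oa * oi * (V - E_K);
  const double g_Kur = 0.005 + 0.05 / (1.0 + std::exp((V - 15.0) / -13.0));
  const double i_Kur = f[5] * Cm * g_Kur * ua * ua * ua * ui * (V - E_K);
  const double i_Kr = Cm * g_Kr * xr * (V - E_K) /
                      (1.0 + std::exp((V + 15.0) / 22.4));
  const double i_Ks = Cm * g_Ks * xs * xs * (V - E_K);
  const double i_Ca_L = f[4] * Cm * g_Ca_L * d * fg * f_Ca * (V - 65.0);

  const double sigma = (std::exp(Na_o / 67.3) - 1.0) / 7.0;
  const double f_NaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                              0.0365 * sigma * std::exp(-V / RTF));
  const double i_NaK = Cm * i_NaK_max * f_NaK *
                       (1.0 / (1.0 + std::pow(Km_Na_i / Na_i, 1.5))) *
                       (K_o / (K_o + Km_K_o));
  const double expg = std::exp(gamma_ncx * V / RTF);
  const double expg1 = std::exp((gamma_ncx - 1.0) * V / RTF);
  const double i_NaCa = f[1] * Cm * I_NaCa_max *
      (expg * Na_i * Na_i * Na_i * Ca_o - expg1 * Na_o * Na_o * Na_o * Ca_i) /
      ((K_mNa * K_mNa * K_mNa + Na_o * Na_o * Na_o) * (K_mCa + Ca_o) *
       (1.0 + K_sat * expg1));
  const double i_B_Na = Cm * g_B_Na * (V - E_Na);
  const double i_B_Ca = Cm * g_B_Ca * (V - E_Ca);
  const double i_CaP = Cm * i_CaP_max * Ca_i / (0.0005 + Ca_i);

  // --- SR fluxes (mM/ms) ---
  const double i_rel = K_rel * u * u * v * w * (Ca_rel - Ca_i);
  const double i_tr = (Ca_up - Ca_rel) / tau_tr;
  const double i_up = I_up_max / (1.0 + K_up / Ca_i);
  const double i_up_leak = I_up_max * Ca_up / Ca_up_max;

  // --- gate kinetics ---
  double a, b;
  // m
  a = (std::fabs(V + 47.13) < 1e-10) ? 3.2
      : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  b = 0.08 * std::exp(-V / 11.0);
  inf[0] = a / (a + b); tau[0] = 1.0 / (a + b);
  // h
  if (V < -40.0) {
    a = 0.135 * std::exp((V + 80.0) / -6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  } else {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
  }
  inf[1] = a / (a + b); tau[1] = 1.0 / (a + b);
  // j
  if (V < -40.0) {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
        (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) /
        (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  inf[2] = a / (a + b); tau[2] = 1.0 / (a + b);
  // oa
  a = 0.65 / (std::exp((V + 10.0) / -8.5) + std::exp((V - 30.0) / -59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[3] = 1.0 / (1.0 + std::exp((V + 20.47) / -17.54));
  tau[3] = 1.0 / ((a + b) * K_Q10);
  // oi
  a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  b = 1.0 / (35.56 + std::exp((V + 1.26) / -7.44));
  inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  tau[4] = 1.0 / ((a + b) * K_Q10);
  // ua
  a = 0.65 / (std::exp((V + 10.0) / -8.5) + std::exp((V - 30.0) / -59.0));
  b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[5] = 1.0 / (1.0 + std::exp((V + 30.3) / -9.6));
  tau[5] = 1.0 / ((a + b) * K_Q10);
  // ui
  a = 1.0 / (21.0 + std::exp((V - 185.0) / -28.0));
  b = std::exp((V - 158.0) / 16.0);
  inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  tau[6] = 1.0 / ((a + b) * K_Q10);
  // xr
  a = (std::fabs(V + 14.1) < 1e-10) ? 0.0015
      : 0.0003 * (V + 14.1) / (1.0 - std::exp((V + 14.1) / -5.0));
  b = (std::fabs(V - 3.3328) < 1e-10) ? 3.7836118e-4
      : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  inf[7] = 1.0 / (1.0 + std::exp((V + 14.1) / -6.5));
  tau[7] = 1.0 / (a + b);
  // xs
  a = (std::fabs(V - 19.9) < 1e-10) ? 0.00068
      : 4e-5 * (V - 19.9) / (1.0 - std::exp((V - 19.9) / -17.0));
  b = (std::fabs(V - 19.9) < 1e-10) ? 0.000315
      : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp((V - 19.9) / -12.7));
  tau[8] = 0.5 / (a + b);
  // d
  inf[9] = 1.0 / (1.0 + std::exp((V + 10.0) / -8.0));
  tau[9] = (std::fabs(V + 10.0) < 1e-10)
      ? 4.579 / (1.0 + std::exp((V + 10.0) / -6.24))
      : (1.0 - std::exp((V + 10.0) / -6.24)) /
        (0.035 * (V + 10.0) * (1.0 + std::exp((V + 10.0) / -6.24)));
  // f
  inf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0))
                   + 0.02);
  // f_Ca
  inf[11] = 1.0 / (1.0 + Ca_i / 0.00035);
  tau[11] = tau_f_Ca;
  // u, v (release gating driven by Fn)
  const double Fn = 1e3 * (1e-15 * V_rel * i_rel -
                           1e-15 / (2.0 * Frdy) * (0.5 * i_Ca_L - 0.2 * i_NaCa));
  inf[12] = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
  tau[12] = tau_u;
  inf[13] = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 1.367e-15));
  tau[13] = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 1.367e-15));
  // w
  inf[14] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  tau[14] = (std::fabs(V - 7.9) < 1e-10)
      ? 6.0 * 0.2 / 1.3
      : 6.0 * (1.0 - std::exp(-(V - 7.9) / 5.0)) /
        ((1.0 + 0.3 * std::exp(-(V - 7.9) / 5.0)) * (V - 7.9));

  // --- concentration rates (mM/ms) ---
  conc_dot[0] = (-3.0 * i_NaK - 3.0 * i_NaCa - i_B_Na - i_Na) / (V_i * Frdy);
  conc_dot[1] = (2.0 * i_NaK - (i_K1 + i_to + i_Kur + i_Kr + i_Ks)) /
                (V_i * Frdy);
  const double B1 = (2.0 * i_NaCa - (i_CaP + i_Ca_L + i_B_Ca)) /
                    (2.0 * V_i * Frdy) +
                    (V_up * (i_up_leak - i_up) + i_rel * V_rel) / V_i;
  const double B2 = 1.0 +
      TRPN_max * Km_TRPN / ((Ca_i + Km_TRPN) * (Ca_i + Km_TRPN)) +
      CMDN_max * Km_CMDN / ((Ca_i + Km_CMDN) * (Ca_i + Km_CMDN));
  conc_dot[2] = B1 / B2;
  conc_dot[3] = i_up - i_up_leak - i_tr * V_rel / V_up;
  conc_dot[4] = (i_tr - i_rel) /
      (1.0 + CSQN_max * Km_CSQN / ((Ca_rel + Km_CSQN) * (Ca_rel + Km_CSQN)));

  if (cur != nullptr) {
    cur[0] = i_Na;  cur[1] = i_K1;  cur[2] = i_to;  cur[3] = i_Kur;
    cur[4] = i_Kr;  cur[5] = i_Ks;  cur[6] = i_Ca_L; cur[7] = i_CaP;
    cur[8] = i_NaK; cur[9] = i_NaCa; cur[10] = i_B_Na; cur[11] = i_B_Ca;
  }

  return -(i_Na + i_K1 + i_to + i_Kur + i_Kr + i_Ks + i_B_Na + i_B_Ca +
           i_NaK + i_CaP + i_NaCa + i_Ca_L + i_stim) / Cm;
}

// One Rush-Larsen (gates) + forward-Euler (V, concentrations) step in place.
// Returns dV/dt evaluated at the pre-step state.
static inline double crn_step(double* y, const double* f, double i_stim,
                              double dt) {
  double inf[N_GATE], tau[N_GATE], conc_dot[5];
  const double dV = crn_core(y, f, i_stim, inf, tau, conc_dot, nullptr);
  for (int g = 0; g < N_GATE; ++g) {
    y[1 + g] = inf[g] + (y[1 + g] - inf[g]) * std::exp(-dt / tau[g]);
  }
  y[0] += dt * dV;
  for (int c = 0; c < 5; ++c) y[16 + c] += dt * conc_dot[c];
  return dV;
}

static void check_state(const NumericVector& y) {
  if (y.size() != N_STATE) stop("state must have %d elements", N_STATE);
  for (int k = 0; k < N_STATE; ++k) {
    if (!R_finite(y[k])) stop("non-finite state variable at index %d", k + 1);
  }
}

static void check_factors(const NumericVector& f) {
  if (f.size() != 6) stop("scaling must have 6 factors");
  for (int k = 0; k < 6; ++k) {
    if (!R_finite(f[k]) || f[k] <= 0) stop("scaling factors must be > 0");
  }
}

// [[Rcpp::export]]
NumericVector crn_resting_state_cpp() {
  NumericVector y = NumericVector::create(
      -81.18, 2.908e-3, 9.649e-1, 9.775e-1, 3.043e-2, 9.992e-1, 4.966e-3,
      9.986e-1, 3.296e-5, 1.869e-2, 1.367e-4, 9.996e-1, 7.755e-1, 2.35e-112,
      1.0, 9.992e-1, 1.117e1, 1.39e2, 1.013e-4, 1.488, 1.488);
  return y;
}

// [[Rcpp::export]]
NumericVector crn_rates_cpp(NumericVector state, NumericVector factors,
                            double i_stim) {
  check_state(state);
  check_factors(factors);
  double inf[N_GATE], tau[N_GATE], conc_dot[5];
  NumericVector out(N_STATE);
  out[0] = crn_core(REAL(state), REAL(factors), i_stim, inf, tau, conc_dot,
                    nullptr);
  for (int g = 0; g < N_GATE; ++g) out[1 + g] = (inf[g] - state[1 + g]) / tau[g];
  for (int c = 0; c < 5; ++c) out[16 + c] = conc_dot[c];
  return out;
}

// [[Rcpp::export]]
NumericVector crn_currents_cpp(NumericVector state, NumericVector factors) {
  check_state(state);
  check_factors(factors);
  double inf[N_GATE], tau[N_GATE], conc_dot[5], cur[12];
  crn_core(REAL(state), REAL(factors), 0.0, inf, tau, conc_dot, cur);
  NumericVector out(12);
  for (int k = 0; k < 12; ++k) out[k] = cur[k];
  out.attr("names") = CharacterVector::create(
      "i_Na", "i_K1", "i_to", "i_Kur", "i_Kr", "i_Ks", "i_CaL", "i_CaP",
      "i_NaK", "i_NaCa", "i_B_Na", "i_B_Ca");
  return out;
}

// Adaptive dt rule shared by both integrators: fine step while any membrane
// is in its upstroke (|dV/dt| > slope_thresh), coarse step otherwise.
static inline double pick_dt(double max_slope, double dt_min, double dt_max,
                             double slope_thresh) {
  return (max_slope > slope_thresh) ? dt_min : dt_max;
}

// [[Rcpp::export]]
List integrate_cell_cpp(NumericVector state, NumericVector factors,
                        NumericVector stim_times, double stim_duration,
                        double stim_amplitude, double duration,
                        double dt_min, double dt_max, double out_dt,
                        double slope_thresh) {
  check_state(state);
  check_factors(factors);
  if (duration < 0) stop("duration must be >= 0");
  std::vector<double> y(state.begin(), state.end());
  const double* f = REAL(factors);

  const int n_out = (int)std::floor(duration / out_dt + 1e-9) + 1;
  NumericVector times(duration == 0 ? 0 : n_out);
  NumericVector vm(duration == 0 ? 0 : n_out);
  if (duration == 0) {
    return List::create(_["times"] = times, _["vm"] = vm,
                        _["state"] = clone(state));
  }

  double t = 0.0, max_slope = 1e9; // start fine in case of immediate stimulus
  int k_out = 0;
  times[0] = 0.0; vm[0] = y[0]; ++k_out;
  const int n_stim = stim_times.size();

  while (t < duration - 1e-9) {
    double dt = pick_dt(max_slope, dt_min, dt_max, slope_thresh);
    if (t + dt > duration) dt = duration - t;
    // snap to the next stimulus onset so pulses are not skipped
    for (int s = 0; s < n_stim; ++s) {
      if (stim_times[s] > t + 1e-9 && stim_times[s] < t + dt - 1e-9) {
        dt = stim_times[s] - t;
        break;
      }
    }
    double i_stim = 0.0;
    for (int s = 0; s < n_stim; ++s) {
      if (t >= stim_times[s] - 1e-9 && t < stim_times[s] + stim_duration - 1e-9)
        i_stim = stim_amplitude;
    }
    const double dV = crn_step(y.data(), f, i_stim, dt);
    max_slope = std::fabs(dV);
    if (!std::isfinite(y[0]) || std::fabs(y[0]) > 200.0)
      stop("numerical blow-up at t = %.3f ms (vm = %g mV)", t, y[0]);
    t += dt;
    if (k_out < n_out && t >= k_out * out_dt - 1e-9) {
      times[k_out] = t; vm[k_out] = y[0]; ++k_out;
    }
  }
  // in case rounding left the final sample unwritten
  if (k_out < n_out) { times[k_out] = t; vm[k_out] = y[0]; ++k_out; }

  NumericVector final_state(y.begin(), y.end());
  final_state.attr("names") = state.attr("names");
  return List::create(_["times"] = times, _["vm"] = vm,
                      _["state"] = final_state);
}

// Monodomain operator-splitting loop. L is the diffusion operator
// (dV/dt += L V, units 1/ms) as a dgCMatrix decomposed into its slots.
// Events: parallel vectors (start, duration, amplitude) with a list of
// 0-based node index vectors. Reaction via Rush-Larsen/Euler, diffusion via
// forward Euler sub-steps bounded by the operator's Gershgorin radius.
// [[Rcpp::export]]
List run_monodomain_cpp(NumericMatrix states, NumericMatrix factors,
                        IntegerVector Lp, IntegerVector Li, NumericVector Lx,
                        NumericVector ev_start, NumericVector ev_dur,
                        NumericVector ev_amp, List ev_nodes,
                        double duration, double dt_min, double dt_max,
                        double out_dt, double slope_thresh) {
  const int n = states.nrow();
  if (states.ncol() != N_STATE) stop("states must be n x %d", N_STATE);
  if (factors.nrow() != n || factors.ncol() != 6) stop("factors must be n x 6");
  if (Lp.size() != n + 1) stop("operator dimension mismatch");
  if (duration <= 0) stop("duration must be > 0");
  const int n_ev = ev_start.size();

  // column-major copy of states for cache-friendly per-node access
  std::vector<double> Y(n * N_STATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < N_STATE; ++k) Y[i * N_STATE + k] = states(i, k);
  std::vector<double> F(n * 6);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 6; ++k) F[i * 6 + k] = factors(i, k);

  // diffusion stability bound from |diagonal| (row sums are zero, so the
  // Gershgorin interval is [-2|L_ii|, 0])
  double max_diag = 0.0;
  for (int jcol = 0; jcol < n; ++jcol) {
    for (int k = Lp[jcol]; k < Lp[jcol + 1]; ++k) {
      if (Li[k] == jcol) {
        const double a = std::fabs(Lx[k]);
        if (a > max_diag) max_diag = a;
      }
    }
  }
  const double dt_diff_max = (max_diag > 0) ? 0.9 / max_diag : R_PosInf;

  const int n_out = (int)std::floor(duration / out_dt + 1e-9) + 1;
  NumericMatrix movie(n, n_out);
  NumericVector out_times(n_out);
  for (int i = 0; i < n; ++i) movie(i, 0) = Y[i * N_STATE];
  out_times[0] = 0.0;
  int k_out = 1;

  std::vector<double> stim(n), v0(n), lv(n);
  double t = 0.0, max_slope = 1e9;
  long n_steps = 0;

  while (t < duration - 1e-9) {
    double dt = pick_dt(max_slope, dt_min, dt_max, slope_thresh);
    if (t + dt > duration) dt = duration - t;
    for (int e = 0; e < n_ev; ++e) {
      if (ev_start[e] > t + 1e-9 && ev_start[e] < t + dt - 1e-9)
        dt = std::min(dt, ev_start[e] - t);
    }

    // stimulus currents for this step
    std::fill(stim.begin(), stim.end(), 0.0);
    for (int e = 0; e < n_ev; ++e) {
      if (t >= ev_start[e] - 1e-9 && t < ev_start[e] + ev_dur[e] - 1e-9) {
        IntegerVector nodes = ev_nodes[e];
        for (int q = 0; q < nodes.size(); ++q) stim[nodes[q]] += ev_amp[e];
      }
    }

    // reaction
    max_slope = 0.0;
    for (int i = 0; i < n; ++i) {
      const double dV = crn_step(&Y[i * N_STATE], &F[i * 6], stim[i], dt);
      const double a = std::fabs(dV);
      if (a > max_slope) max_slope = a;
      const double vi = Y[i * N_STATE];
      if (!std::isfinite(vi) || std::fabs(vi) > 200.0)
        stop("numerical blow-up at t = %.3f ms, node %d (vm = %g mV)",
             t, i + 1, vi);
    }

    // diffusion (explicit, sub-stepped for stability)
    if (max_diag > 0) {
      const int n_sub = (int)std::ceil(dt / dt_diff_max);
      const double h = dt / n_sub;
      for (int s = 0; s < n_sub; ++s) {
        for (int i = 0; i < n; ++i) { v0[i] = Y[i * N_STATE]; lv[i] = 0.0; }
        for (int jcol = 0; jcol < n; ++jcol) {
          const double vj = v0[jcol];
          if (vj == 0.0) continue;
          for (int k = Lp[jcol]; k < Lp[jcol + 1]; ++k)
            lv[Li[k]] += Lx[k] * vj;
        }
        for (int i = 0; i < n; ++i) Y[i * N_STATE] += h * lv[i];
      }
    }

    t += dt;
    ++n_steps;
    if (k_out < n_out && t >= k_out * out_dt - 1e-9) {
      for (int i = 0; i < n; ++i) movie(i, k_out) = Y[i * N_STATE];
      out_times[k_out] = t;
      ++k_out;
    }
    if ((n_steps & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  if (k_out < n_out) {
    for (int i = 0; i < n; ++i) movie(i, k_out) = Y[i * N_STATE];
    out_times[k_out] = t;
    ++k_out;
  }

  NumericMatrix final_states(n, N_STATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < N_STATE; ++k) final_states(i, k) = Y[i * N_STATE + k];

  return List::create(_["vm"] = movie, _["times"] = out_times,
                      _["states"] = final_states,
                      _["n_steps"] = (double)n_steps);
}
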