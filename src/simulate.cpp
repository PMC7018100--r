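#include <Rcpp.h>
using namespace Rcpp;

// Single-trial Euler-Maruyama integration of the seven-variable circuit:
// two sensorimotor gating variables, two OU noise currents, one
// uncertainty-monitoring rate, two hand rates. Units: ms, nA, Hz; the
// gamma*H gating products divide rates by 1000 (Hz -> events/ms).
// RNG: uses R's generator, so a set.seed() before the call makes the
// trial bit-reproducible.

static inline double io_gain_c(double x, double a, double b, double d,
                               double G_S) {
  double z = a * x - b;
  double dz = d * z;
  if (std::fabs(dz) < 1e-4) {
    // series for t/(1 - e^-t) about t = 0
    return (G_S / d) * (1.0 + dz / 2.0 + dz * dz / 12.0 -
                        dz * dz * dz * dz / 720.0);
  }
  if (dz > 500.0) return G_S * z;  // exponential underflow branch
  return G_S * z / (1.0 - std::exp(-dz));
}

// [[Rcpp::export]]
List sim_trial_cpp(List par, double coherence, bool correct_right,
                   bool noise_on, bool store_traces) {
  const double tau_S = par["tau_S"], tau_h = par["tau_h"],
               tau_mc = par["tau_mc"];
  const double a = par["a"], b = par["b"], d = par["d"];
  const double I_0 = par["I_0"], J_N_ii = par["J_N_ii"],
               J_N_ij = par["J_N_ij"];
  const double mu_0 = par["mu_0"], J_A_ext = par["J_A_ext"];
  const double J_mc0 = par["J_mc0"], J_VHU = par["J_VHU"];
  const double J_N_LR = par["J_N_LR"], J_N_RL = par["J_N_RL"];
  const double S_th = par["S_th"], H_th = par["H_th"],
               H_target = par["H_target"];
  const double G_S = par["G_S"], gamma = par["gamma"];
  const double sigma_noise = par["sigma_noise"], tau_noise = par["tau_noise"];
  const double g_pre = par["g_pre"], g_post = par["g_post"],
               g_hand = par["g_hand"], g_gate = par["g_gate"];
  const double C_pos = par["C_pos"];
  const double dt = par["dt"];
  const double t_gate = par["t_gate"], t_stim = par["t_stim"],
               t_max = par["t_max"];
  const double S_init = par["S_init"];
  const double tau_r = par["tau_r"];

  const int n_steps = (int)std::lround(t_max / dt);
  const double q = std::fabs(C_pos) / H_th;
  const double stim_base = J_A_ext * mu_0;
  const double noise_coef =
      noise_on ? sigma_noise * std::sqrt(2.0 / tau_noise) * std::sqrt(dt) : 0.0;

  double S_L = S_init, S_R = S_init;
  double Ie_L = 0.0, Ie_R = 0.0;
  double y_u = 0.0, y_l = 0.0, y_r = 0.0;
  // filtered population-rate readout (threshold detection and downstream
  // input); initialised at the noise-free resting rate
  double x0 = J_N_ii * S_init - J_N_ij * S_init + I_0;
  double Hf_L = io_gain_c(x0, a, b, d, G_S);
  double Hf_R = Hf_L;

  bool decided = false;
  double t_dec = NA_REAL;
  int choice_init = 0;  // 0 none, 1 left, 2 right
  int n_tie_breaks = 0;
  double peak_yu = 0.0;
  int n_rev = 0, last_ep_sign = 0;
  bool motor_complete = false;
  double motor_end = NA_REAL, t_cursor = NA_REAL;
  int n_clip = 0;
  double t_end = t_max;

  NumericMatrix tr;
  int tr_n = 0;
  if (store_traces) tr = NumericMatrix(n_steps, 9);

  double t = 0.0;
  for (int k = 0; k < n_steps; ++k) {
    // stimulus currents
    double I_L = 0.0, I_R = 0.0;
    if (t >= 0.0 && t < t_stim) {
      double hi = stim_base * (1.0 + coherence);
      double lo = stim_base * (1.0 - coherence);
      if (correct_right) { I_R = hi; I_L = lo; } else { I_L = hi; I_R = lo; }
    }

    // total currents and rates
    double x_L = J_N_ii * S_L - J_N_ij * S_R + I_0 + I_L + J_mc0 * y_u + Ie_L;
    double x_R = J_N_ii * S_R - J_N_ij * S_L + I_0 + I_R + J_mc0 * y_u + Ie_R;
    double H_L = io_gain_c(x_L, a, b, d, G_S);
    double H_R = io_gain_c(x_R, a, b, d, G_S);
    if (H_L < 0.0) H_L = 0.0;
    if (H_R < 0.0) H_R = 0.0;
    if (tau_r <= dt) { Hf_L = H_L; Hf_R = H_R; }  // unsmoothed readout

    // decision detection on the (optionally smoothed) rates at time t
    if (!decided && (Hf_L >= S_th || Hf_R >= S_th)) {
      decided = true;
      t_dec = t;
      if (Hf_L > Hf_R) choice_init = 1;
      else if (Hf_R > Hf_L) choice_init = 2;
      else { choice_init = (unif_rand() < 0.5) ? 1 : 2; ++n_tie_breaks; }
    }

    // gating schedule
    double g_u = decided ? g_post : (t < t_gate ? g_pre : g_gate);
    double g_h = decided ? 0.0 : g_hand;

    if (store_traces) {
      tr(tr_n, 0) = t;   tr(tr_n, 1) = S_L; tr(tr_n, 2) = S_R;
      tr(tr_n, 3) = Hf_L; tr(tr_n, 4) = Hf_R; tr(tr_n, 5) = y_u;
      tr(tr_n, 6) = y_l; tr(tr_n, 7) = y_r;
      tr(tr_n, 8) = q * (y_l - y_r);
      ++tr_n;
    }

    // drifts (per ms)
    double dS_L = -S_L / tau_S + (1.0 - S_L) * gamma * (H_L / 1000.0);
    double dS_R = -S_R / tau_S + (1.0 - S_R) * gamma * (H_R / 1000.0);
    double in_u = J_VHU * (Hf_L + Hf_R) - g_u;
    double dy_u = ((in_u > 0.0 ? in_u : 0.0) - y_u) / tau_mc;
    double in_l = Hf_L - J_N_LR * y_r - g_h;
    double in_r = Hf_R - J_N_RL * y_l - g_h;
    double dy_l = ((in_l > 0.0 ? in_l : 0.0) - y_l) / tau_h;
    double dy_r = ((in_r > 0.0 ? in_r : 0.0) - y_r) / tau_h;

    // Euler-Maruyama update
    S_L += dt * dS_L;
    S_R += dt * dS_R;
    if (tau_r > dt) {
      Hf_L += dt * (H_L - Hf_L) / tau_r;
      Hf_R += dt * (H_R - Hf_R) / tau_r;
    }
    y_u += dt * dy_u;
    y_l += dt * dy_l;
    y_r += dt * dy_r;
    if (noise_on) {
      Ie_L += -Ie_L / tau_noise * dt + noise_coef * norm_rand();
      Ie_R += -Ie_R / tau_noise * dt + noise_coef * norm_rand();
    } else {
      Ie_L += -Ie_L / tau_noise * dt;
      Ie_R += -Ie_R / tau_noise * dt;
    }
    if (S_L < 0.0) { S_L = 0.0; ++n_clip; }
    if (S_L > 1.0) { S_L = 1.0; ++n_clip; }
    if (S_R < 0.0) { S_R = 0.0; ++n_clip; }
    if (S_R > 1.0) { S_R = 1.0; ++n_clip; }

    t += dt;

    if (!(R_finite(S_L) && R_finite(S_R) && R_finite(y_u) && R_finite(y_l) &&
          R_finite(y_r) && R_finite(Ie_L) && R_finite(Ie_R))) {
      stop("non-finite state at t = %f ms; trial aborted", t);
    }

    if (y_u > peak_yu) peak_yu = y_u;

    if (decided) {
      // streaming dominance-episode reversal count (|y_HL - y_HR| > 2 Hz)
      double delta = y_l - y_r;
      if (delta > 2.0 || delta < -2.0) {
        int s = delta > 0.0 ? 1 : -1;
        if (last_ep_sign == 0) last_ep_sign = s;
        else if (s != last_ep_sign) { ++n_rev; last_ep_sign = s; }
      }
      if (!R_finite(t_cursor) && std::fabs(q * (y_l - y_r)) >= C_pos)
        t_cursor = t;
      if (!motor_complete && (y_l >= H_target || y_r >= H_target)) {
        motor_complete = true;
        motor_end = t;
      }
    }
  }

  int choice_final = 0;
  if (decided) {
    if (y_l > y_r) choice_final = 1;
    else if (y_r > y_l) choice_final = 2;
    else choice_final = choice_init;
  }

  List out = List::create(
      _["decided"] = decided,
      _["choice_initial"] = choice_init,
      _["choice_final"] = choice_final,
      _["decision_time_raw"] = t_dec,
      _["response_time"] = decided ? t_dec - t_stim : NA_REAL,
      _["peak_uncertainty"] = peak_yu,
      _["n_reversals"] = n_rev,
      _["is_com"] = decided && n_rev >= 1,
      _["motor_complete"] = motor_complete,
      _["motor_end_time"] = motor_end,
      _["t_cursor_target"] = t_cursor,
      _["t_end"] = t_end,
      _["n_clip"] = n_clip,
      _["n_tie_breaks"] = n_tie_breaks);
  if (store_traces) {
    out["trace"] = tr(Range(0, tr_n - 1), Range(0, 8));
  }
  return out;
}
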