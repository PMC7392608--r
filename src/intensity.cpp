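#include <Rcpp.h>
using namespace Rcpp;

// Full within-trial loop of the intensity model. Mirrors the R reference
// implementation (intensity_trial_r) step for step: all derivatives are
// evaluated on the pre-update state (synchronous Euler step), history
// buffers store pre-update values, learning uses post-update errors and is
// confined to the reward window.
// [[Rcpp::export]]
List intensity_trial_cpp(NumericVector w, int n_intervals,
                         IntegerVector active_blocks,
                         double q, double h, double sg, double sh,
                         double tau, double tau_delta, double dt,
                         double t_stim, double t_reward, double t_end,
                         double reward_duration, double interval,
                         double lambda, double alpha_v,
                         double alpha_g, double alpha_h,
                         double alpha_sg, double alpha_sh,
                         double sigma_floor,
                         int env_type, double sigma_r, double reward_value,
                         double sigma_a, double eps_r, double eps_a,
                         bool depleted, bool learn_valuation, bool learn_actor,
                         bool actor_on, bool record) {
  const int n_steps = (int) std::lround(t_end / dt);
  const int k_stim  = (int) std::lround(t_stim / dt);
  const int k_rew   = (int) std::lround(t_reward / dt);
  const int k_rend  = (int) std::lround((t_reward + reward_duration) / dt);
  const int lag_v   = (int) std::lround(interval / dt);
  const int lag_e   = (int) std::lround((interval + 3.0 * tau) / dt);
  const int n_w     = w.size();

  NumericVector wv = clone(w);
  std::vector<double> e(n_w, 0.0), sv(n_w, 0.0);
  std::vector<double> v_buf(lag_v, 0.0);
  std::vector<double> e_buf((size_t) lag_e * n_w, 0.0);

  double v = 0.0, dv = 0.0, rs = 0.0;
  double a = 0.0, dg = 0.0, dh = 0.0;
  double planned = 0.0, executed = 0.0, r_trial = 0.0;
  double max_dv = R_NegInf, max_dg = R_NegInf, max_dh = R_NegInf;
  double dh_exec = 0.0;

  NumericMatrix traj = record ? NumericMatrix(n_steps, 8) : NumericMatrix(0, 0);

  for (int k = 0; k < n_steps; ++k) {
    const double t = k * dt;
    const double s = (k >= k_stim && actor_on) ? 1.0 : 0.0;

    // interval-indicator state vector
    std::fill(sv.begin(), sv.end(), 0.0);
    const double t_since = t - t_stim;
    if (t_since >= 0.0) {
      const int idx = (int) std::floor(t_since / interval);
      if (idx < n_intervals) {
        for (int b = 0; b < active_blocks.size(); ++b)
          sv[active_blocks[b] * n_intervals + idx] = 1.0;
      }
    }

    if (k == k_rew) {
      planned = a;
      executed = actor_on ? a + sigma_a * eps_a : 0.0;
      switch (env_type) {
        case 0: r_trial = 5.0 * std::tanh(3.0 * executed / 5.0) - executed +
                          sigma_r * eps_r; break;
        case 1: r_trial = -executed; break;
        default: r_trial = reward_value + sigma_r * eps_r; break;
      }
      a = executed;
    }
    const double r0 = (k >= k_rew && k < k_rend) ? r_trial : 0.0;

    // lagged reads (zero-padded at trial start via zero-initialised buffers)
    const int slot_v = k % lag_v;
    const int slot_e = k % lag_e;
    const double v_lag = v_buf[slot_v];

    double wsv = 0.0;
    for (int j = 0; j < n_w; ++j) wsv += wv[j] * sv[j];

    const double d_v  = wsv - v;
    const double d_dv = rs + v - v_lag - dv;
    const double d_rs = r0 - rs;
    const double d_dg = rs + v - a * q * s - sg * dg;
    const double d_dh = a - h * s - dh;
    const double d_a  = dg * q * s + (h * s - a) / sh;

    v_buf[slot_v] = v;
    double *e_row = &e_buf[(size_t) slot_e * n_w];
    std::vector<double> e_lag(e_row, e_row + n_w);
    for (int j = 0; j < n_w; ++j) {
      const double d_e = lambda * e_lag[j] + sv[j] - e[j];
      e_row[j] = e[j];
      e[j] += (dt / tau) * d_e;
    }

    v  += (dt / tau) * d_v;
    dv += (dt / tau_delta) * d_dv;
    rs += (dt / tau) * d_rs;
    dg += (dt / tau_delta) * d_dg;
    dh += (dt / tau_delta) * d_dh;
    if (k < k_rew && actor_on) a += (dt / tau) * d_a;
    if (depleted) { dv = 0.0; dg = 0.0; dh = 0.0; }
    const double g_input = dg * q * s;  // striatal drive, pre-learning gain

    // the valuation critic learns at every step; pairing delta_v with the
    // lagged trace makes the error correct the preceding interval's
    // prediction (standard TD credit assignment) and keeps learning stable
    if (learn_valuation) {
      for (int j = 0; j < n_w; ++j) {
        wv[j] += dt * alpha_v * dv * e_lag[j];
        if (wv[j] < 0.0) wv[j] = 0.0;
      }
    }
    if (learn_actor && k >= k_rew && k < k_rend) {
      const double q_new  = q + dt * alpha_g * dg * executed * s;
      const double h_new  = h + dt * alpha_h * dh * s;
      const double sg_new = sg + dt * alpha_sg * (sg * sg * dg * dg - sg);
      const double sh_new = sh + dt * alpha_sh * (dh * dh - sh);
      q = q_new;
      h = h_new;
      sg = std::max(sg_new, sigma_floor);
      sh = std::max(sh_new, sigma_floor);
    }

    if (dv > max_dv) max_dv = dv;
    if (dg > max_dg) max_dg = dg;
    if (dh > max_dh) max_dh = dh;
    if (k == k_rend - 1) dh_exec = dh;

    if (!std::isfinite(a) || !std::isfinite(dg) || !std::isfinite(dh)) {
      stop("integration diverged at step %d (t = %.3f)", k, t);
    }

    if (record) {
      traj(k, 0) = t;  traj(k, 1) = a;   traj(k, 2) = dv;
      traj(k, 3) = dg; traj(k, 4) = dh;  traj(k, 5) = v;
      traj(k, 6) = rs; traj(k, 7) = g_input;
    }
  }

  return List::create(
    _["q"] = q, _["h"] = h, _["sg"] = sg, _["sh"] = sh, _["w"] = wv,
    _["planned"] = planned, _["executed"] = executed, _["reward"] = r_trial,
    _["max_dv"] = max_dv, _["max_dg"] = max_dg, _["max_dh"] = max_dh,
    _["dh_exec"] = dh_exec, _["trajectory"] = traj);
}

// Planning-phase dynamics of the two-action choice model: competitive
// gradient dynamics on the action intensities with precision-weighted
// goal-directed and habit drives, intensities clipped to [0, 1]. The value
// estimate relaxes from 0 toward its equilibrium w.s during planning.
// [[Rcpp::export]]
List choice_plan_cpp(NumericVector Qs, NumericVector Hs,
                     double sg, double sh, double comp, double v_eq,
                     double tau, double tau_delta, double dt, int n_steps,
                     bool depleted, bool record) {
  double a1 = 0.0, a2 = 0.0, dg = 0.0, v = 0.0;
  double max_dg = R_NegInf, max_dh = R_NegInf;
  NumericMatrix traj = record ? NumericMatrix(n_steps, 7) : NumericMatrix(0, 0);

  for (int k = 0; k < n_steps; ++k) {
    const double aQs = a1 * Qs[0] + a2 * Qs[1];
    const double d_dg = v - aQs - sg * dg;
    const double d_a1 = dg * Qs[0] + (Hs[0] - a1) / sh - comp * a2;
    const double d_a2 = dg * Qs[1] + (Hs[1] - a2) / sh - comp * a1;
    const double d_v  = v_eq - v;

    dg += (dt / tau_delta) * d_dg;
    a1 += (dt / tau) * d_a1;
    a2 += (dt / tau) * d_a2;
    v  += (dt / tau) * d_v;
    if (a1 < 0.0) a1 = 0.0; else if (a1 > 1.0) a1 = 1.0;
    if (a2 < 0.0) a2 = 0.0; else if (a2 > 1.0) a2 = 1.0;
    if (depleted) dg = 0.0;

    if (dg > max_dg) max_dg = dg;
    const double dh1 = a1 - Hs[0], dh2 = a2 - Hs[1];
    const double dh_max = dh1 > dh2 ? dh1 : dh2;
    if (dh_max > max_dh) max_dh = dh_max;
    if (!std::isfinite(a1) || !std::isfinite(a2) || !std::isfinite(dg)) {
      stop("integration diverged at step %d", k);
    }

    if (record) {
      traj(k, 0) = k * dt;
      traj(k, 1) = a1; traj(k, 2) = a2; traj(k, 3) = dg;
      traj(k, 4) = dg * Qs[0]; traj(k, 5) = Hs[0] / sh; traj(k, 6) = v;
    }
  }

  return List::create(
    _["a"] = NumericVector::create(a1, a2), _["delta_g"] = dg,
    _["v_end"] = v, _["max_dg"] = max_dg, _["max_dh"] = max_dh,
    _["trajectory"] = traj);
}
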