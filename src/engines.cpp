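// Clocked LIF network engines for the two shipped models.
//
// These mirror, step for step, the plain-R reference engine in R/engine.R:
//   (1) conductances decay (forward Euler) and receive the previous step's
//       presynaptic spikes (one-step delivery delay);
//   (2) external Poisson sources draw this step's spikes (R's RNG stream,
//       unit-by-unit per step, so seeding is shared with the R side);
//   (3) one Euler membrane step per population; threshold crossings reset to
//       rest and start the refractory clock, during which the voltage is
//       held and not integrated while conductances keep decaying;
//   (4) plasticity traces advance on this step's conductances/spikes, then
//       spike-triggered weight updates apply, so a spike sees the current
//       trace.
//
// All quantities are in mV, ms, nS, megaohm, nA. R[megaohm]*g[nS] carries a
// factor 1e-3; R[megaohm]*I[nA] is directly mV. Both engines take and return
// a full state list, so protocols are chained by resuming state from R.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct SpikeLog {
  std::vector<int> pop;
  std::vector<int> id;
  std::vector<double> t;
  void add(int p, int i, double ti) {
    pop.push_back(p);
    id.push_back(i + 1);  // 1-based for R
    t.push_back(ti);
  }
};

// One Euler membrane step for a population; fills spiked[] with this step's
// threshold crossings.
inline void lif_step(std::vector<double>& v, std::vector<double>& refr,
                     const std::vector<char>& clamped,
                     const double* g_exc, const double* g_inh,
                     const double* i_ext, std::vector<char>& spiked,
                     double v_rest, double theta, double r_m, double tau_m,
                     double t_ref, double v_rev_e, double v_rev_i, double dt) {
  const size_t n = v.size();
  for (size_t i = 0; i < n; ++i) {
    spiked[i] = 0;
    if (clamped[i]) { v[i] = v_rest; continue; }
    if (refr[i] > 0) {
      refr[i] = std::max(refr[i] - dt, 0.0);
      v[i] = v_rest;
      continue;
    }
    if (v[i] >= theta) {  // already at threshold: spike without integrating
      spiked[i] = 1;
      v[i] = v_rest;
      refr[i] = t_ref;
      continue;
    }
    double drive = (v_rest - v[i])
      + 1e-3 * r_m * g_exc[i] * (v_rev_e - v[i])
      + 1e-3 * r_m * g_inh[i] * (v_rev_i - v[i])
      + r_m * i_ext[i];
    v[i] += (dt / tau_m) * drive;
    // conductance-based dynamics are reversal-bounded; keep the Euler step
    // inside [V_I, V_E] so extreme conductances cannot destabilize it
    if (v[i] < v_rev_i) v[i] = v_rev_i;
    if (v[i] > v_rev_e) v[i] = v_rev_e;
    if (!std::isfinite(v[i])) stop("non-finite membrane potential (neuron %d)", (int)i + 1);
    if (v[i] >= theta) {
      spiked[i] = 1;
      v[i] = v_rest;
      refr[i] = t_ref;
    }
  }
}

// conductances follow a linear ODE between spikes, so the decay is applied
// exactly (the voltage step stays forward Euler)
inline void decay(std::vector<double>& g, double dt, double tau) {
  const double f = std::exp(-dt / tau);
  for (size_t i = 0; i < g.size(); ++i) g[i] *= f;
}

// g += g_bar * W[, j] for every presynaptic j that spiked last step.
inline void deliver(std::vector<double>& g, const NumericMatrix& w,
                    const std::vector<char>& pre_spiked, double g_bar) {
  const int npost = w.nrow();
  for (int j = 0; j < (int)pre_spiked.size(); ++j) {
    if (!pre_spiked[j]) continue;
    const double* col = &w(0, j);
    for (int i = 0; i < npost; ++i) g[i] += g_bar * col[i];
  }
}

inline std::vector<double> as_vec(SEXP x) {
  NumericVector v(x);
  return std::vector<double>(v.begin(), v.end());
}

// positive modulo without libm's fmod (keeps the binary portable across
// glibc builds)
inline double wrap_pos(double x, double m) { return x - m * std::floor(x / m); }

inline std::vector<char> as_charvec(SEXP x) {
  LogicalVector v(x);
  std::vector<char> out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = v[i] ? 1 : 0;
  return out;
}

}  // namespace

// ---------------------------------------------------------------------------
// Sparse random recurrent network (80E / 20I / 100 external Poisson units).
// rule: 0 = none, 1 = IDIP (multiplicative bound), 2 = iSTDP (additive).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_recurrent_cpp(List state, List params, double duration_ms, double dt,
                       int rule, double rule_on_ms, double record_from_ms,
                       Nullable<LogicalMatrix> ext_spikes_in = R_NilValue,
                       double sample_every_ms = 100.0) {
  // --- unpack parameters
  const double v_rest = params["v_rest"], theta_m = params["theta_m"];
  const double r_m = params["r_m"], tau_m = params["tau_m"], t_ref = params["t_ref"];
  const double g_bar = params["g_bar"], v_rev_e = params["v_rev_exc"],
               v_rev_i = params["v_rev_inh"];
  const double tau_exc = params["tau_exc"], tau_inh = params["tau_inh"];
  const double rate_hz = params["poisson_rate"];
  const double idip_eta = params["idip_eta"], theta_in = params["idip_theta_in"],
               tau_idip = params["idip_tau"], w_max = params["idip_w_max"];
  const double is_eta = params["istdp_eta"], is_alpha = params["istdp_alpha"],
               is_tau = params["istdp_tau"];

  // --- unpack state (copied; the updated copy is returned)
  double t0 = state["t"];
  std::vector<double> v_e = as_vec(state["v_e"]), v_i = as_vec(state["v_i"]);
  std::vector<double> ref_e = as_vec(state["ref_e"]), ref_i = as_vec(state["ref_i"]);
  NumericMatrix w_ee = clone(as<NumericMatrix>(state["w_ee"]));
  NumericMatrix w_ie = clone(as<NumericMatrix>(state["w_ie"]));
  NumericMatrix w_ei = clone(as<NumericMatrix>(state["w_ei"]));
  NumericMatrix w_xe = clone(as<NumericMatrix>(state["w_xe"]));
  NumericMatrix w_xi = clone(as<NumericMatrix>(state["w_xi"]));
  NumericMatrix w_ii = clone(as<NumericMatrix>(state["w_ii"]));
  LogicalMatrix m_ei = state["m_ei"];
  std::vector<double> g_ee = as_vec(state["g_ee"]), g_xe = as_vec(state["g_xe"]);
  std::vector<double> g_ei = as_vec(state["g_ei"]), g_ie = as_vec(state["g_ie"]);
  std::vector<double> g_xi = as_vec(state["g_xi"]), g_ii = as_vec(state["g_ii"]);
  std::vector<double> y = as_vec(state["y"]);
  std::vector<double> x_pre = as_vec(state["x_pre"]), x_post = as_vec(state["x_post"]);
  std::vector<char> sp_e = as_charvec(state["sp_e"]), sp_i = as_charvec(state["sp_i"]);
  std::vector<char> sp_x = as_charvec(state["sp_x"]);

  const int n_e = v_e.size(), n_i = v_i.size(), n_x = sp_x.size();
  const int n_steps = (int)std::lround(duration_ms / dt);
  const double p_spike = rate_hz * dt / 1000.0;

  LogicalMatrix ext_spikes;
  bool scripted = ext_spikes_in.isNotNull();
  if (scripted) {
    ext_spikes = LogicalMatrix(ext_spikes_in);
    if (ext_spikes.nrow() != n_steps || ext_spikes.ncol() != n_x)
      stop("scripted external spikes must be n_steps x n_ext");
  }

  std::vector<char> now_e(n_e), now_i(n_i), now_x(n_x);
  std::vector<double> g_exc_e(n_e), g_exc_i(n_i), zeros_i(n_i, 0.0);
  std::vector<double> i_ext_e(n_e, 0.0), i_ext_i(n_i, 0.0);
  std::vector<char> noclamp_e(n_e, 0), noclamp_i(n_i, 0);

  SpikeLog log;
  log.pop.reserve(1 << 16);
  std::vector<double> y_spk_sum(n_i, 0.0);
  std::vector<int> y_spk_n(n_i, 0);
  std::vector<double> cur_exc_sum(n_e, 0.0), cur_inh_sum(n_e, 0.0);
  long cur_n = 0;
  std::vector<double> trace_t, trace_wei, trace_y;

  const double mask_count = [&]() {
    double c = 0;
    for (int i = 0; i < m_ei.nrow(); ++i)
      for (int j = 0; j < m_ei.ncol(); ++j) c += m_ei(i, j) ? 1 : 0;
    return std::max(c, 1.0);
  }();

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = t0 + (step + 1) * dt;

    // (1) conductance decay + delivery of last step's spikes
    decay(g_ee, dt, tau_exc); decay(g_xe, dt, tau_exc);
    decay(g_ie, dt, tau_exc); decay(g_xi, dt, tau_exc);
    decay(g_ei, dt, tau_inh); decay(g_ii, dt, tau_inh);
    deliver(g_ee, w_ee, sp_e, g_bar);
    deliver(g_ie, w_ie, sp_e, g_bar);
    deliver(g_ei, w_ei, sp_i, g_bar);
    deliver(g_ii, w_ii, sp_i, g_bar);
    deliver(g_xe, w_xe, sp_x, g_bar);
    deliver(g_xi, w_xi, sp_x, g_bar);

    // (2) external Poisson spikes for this step
    if (scripted) {
      for (int j = 0; j < n_x; ++j) now_x[j] = ext_spikes(step, j) ? 1 : 0;
    } else {
      for (int j = 0; j < n_x; ++j) now_x[j] = (unif_rand() < p_spike) ? 1 : 0;
    }

    // (3) membrane steps
    for (int i = 0; i < n_e; ++i) g_exc_e[i] = g_ee[i] + g_xe[i];
    for (int i = 0; i < n_i; ++i) g_exc_i[i] = g_ie[i] + g_xi[i];
    lif_step(v_e, ref_e, noclamp_e, g_exc_e.data(), g_ei.data(), i_ext_e.data(),
             now_e, v_rest, theta_m, r_m, tau_m, t_ref, v_rev_e, v_rev_i, dt);
    lif_step(v_i, ref_i, noclamp_i, g_exc_i.data(), g_ii.data(), i_ext_i.data(),
             now_i, v_rest, theta_m, r_m, tau_m, t_ref, v_rev_e, v_rev_i, dt);

    // (4) plasticity: IDIP trace and iSTDP traces first, then spike updates
    for (int i = 0; i < n_i; ++i)
      y[i] += dt * (-y[i] / tau_idip + g_exc_i[i]);
    if (rule == 2) {
      const double f = 1.0 - dt / is_tau;
      for (int i = 0; i < n_i; ++i) { x_pre[i] *= f; if (now_i[i]) x_pre[i] += 1.0; }
      for (int j = 0; j < n_e; ++j) { x_post[j] *= f; if (now_e[j]) x_post[j] += 1.0; }
    }
    const bool learning = t_now >= rule_on_ms;
    if (learning && rule == 1) {
      for (int i = 0; i < n_i; ++i) {
        if (!now_i[i]) continue;
        const double d = idip_eta * (y[i] - theta_in);
        for (int j = 0; j < n_e; ++j) {
          if (!m_ei(j, i)) continue;
          double w = w_ei(j, i);
          w += (d > 0) ? (w_max - w) * d : w * d;
          w_ei(j, i) = std::min(std::max(w, 0.0), w_max);
        }
      }
    } else if (learning && rule == 2) {
      bool touched = false;
      for (int i = 0; i < n_i; ++i) {
        if (!now_i[i]) continue;
        touched = true;
        for (int j = 0; j < n_e; ++j) {
          if (!m_ei(j, i)) continue;
          w_ei(j, i) += is_eta * (x_post[j] - is_alpha);
        }
      }
      for (int j = 0; j < n_e; ++j) {
        if (!now_e[j]) continue;
        touched = true;
        for (int i = 0; i < n_i; ++i) {
          if (!m_ei(j, i)) continue;
          w_ei(j, i) += is_eta * x_pre[i];
        }
      }
      if (touched) {
        for (int i = 0; i < n_i; ++i)
          for (int j = 0; j < n_e; ++j)
            if (w_ei(j, i) < 0) w_ei(j, i) = 0;
      }
    }

    // recording
    for (int i = 0; i < n_e; ++i) if (now_e[i]) log.add(0, i, t_now);
    for (int i = 0; i < n_i; ++i) {
      if (now_i[i]) {
        log.add(1, i, t_now);
        if (t_now >= record_from_ms) { y_spk_sum[i] += y[i]; y_spk_n[i]++; }
      }
    }
    if (t_now >= record_from_ms) {
      for (int i = 0; i < n_e; ++i) {
        cur_exc_sum[i] += 1e-3 * g_exc_e[i] * (v_rev_e - v_e[i]);
        cur_inh_sum[i] += 1e-3 * g_ei[i] * (v_rev_i - v_e[i]);
      }
      cur_n++;
    }
    if (sample_every_ms > 0 &&
        ((step + 1) % (int)std::lround(sample_every_ms / dt)) == 0) {
      double ws = 0, ys = 0;
      for (int i = 0; i < n_e; ++i)
        for (int j = 0; j < n_i; ++j) if (m_ei(i, j)) ws += w_ei(i, j);
      for (int j = 0; j < n_i; ++j) ys += y[j];
      trace_t.push_back(t_now);
      trace_wei.push_back(ws / mask_count);
      trace_y.push_back(ys / n_i);
    }

    std::swap(sp_e, now_e); std::swap(sp_i, now_i); std::swap(sp_x, now_x);
  }

  List new_state = List::create(
    _["t"] = t0 + n_steps * dt,
    _["v_e"] = v_e, _["v_i"] = v_i, _["ref_e"] = ref_e, _["ref_i"] = ref_i,
    _["w_ee"] = w_ee, _["w_ie"] = w_ie, _["w_ei"] = w_ei,
    _["w_xe"] = w_xe, _["w_xi"] = w_xi, _["w_ii"] = w_ii, _["m_ei"] = m_ei,
    _["g_ee"] = g_ee, _["g_xe"] = g_xe, _["g_ei"] = g_ei,
    _["g_ie"] = g_ie, _["g_xi"] = g_xi, _["g_ii"] = g_ii,
    _["y"] = y, _["x_pre"] = x_pre, _["x_post"] = x_post,
    _["sp_e"] = LogicalVector(sp_e.begin(), sp_e.end()),
    _["sp_i"] = LogicalVector(sp_i.begin(), sp_i.end()),
    _["sp_x"] = LogicalVector(sp_x.begin(), sp_x.end()));

  return List::create(
    _["state"] = new_state,
    _["spike_pop"] = IntegerVector(log.pop.begin(), log.pop.end()),
    _["spike_id"] = IntegerVector(log.id.begin(), log.id.end()),
    _["spike_t"] = NumericVector(log.t.begin(), log.t.end()),
    _["y_spike_sum"] = NumericVector(y_spk_sum.begin(), y_spk_sum.end()),
    _["y_spike_n"] = IntegerVector(y_spk_n.begin(), y_spk_n.end()),
    _["mean_exc_current"] = NumericVector(cur_exc_sum.begin(), cur_exc_sum.end()),
    _["mean_inh_current"] = NumericVector(cur_inh_sum.begin(), cur_inh_sum.end()),
    _["current_n"] = (double)cur_n,
    _["trace_t"] = NumericVector(trace_t.begin(), trace_t.end()),
    _["trace_w_ei"] = NumericVector(trace_wei.begin(), trace_wei.end()),
    _["trace_y"] = NumericVector(trace_y.begin(), trace_y.end()));
}

// ---------------------------------------------------------------------------
// Hippocampal CA3 -> CA1 place-cell network.
// Deterministic given the built state (no Poisson input); the animal moves at
// constant speed on an annular track and both CA3 cells and CA1 excitatory
// cells receive Gaussian place-tuned currents (CA1 with per-neuron amplitude
// offsets). CA3->CA1E weights follow the Hebbian + homeostatic rule; I->E
// weights follow additive IDIP clipped at zero.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_hippocampus_cpp(List state, List params, double duration_ms, double dt,
                         bool hebb_on, bool idip_on, LogicalVector silence,
                         double record_from_ms, double sample_every_ms = 1000.0) {
  const double v_rest = params["v_rest"], theta_m = params["theta_m"];
  const double r_m = params["r_m"], tau_m = params["tau_m"], t_ref = params["t_ref"];
  const double g_bar = params["g_bar"], v_rev_e = params["v_rev_exc"],
               v_rev_i = params["v_rev_inh"];
  const double tau_exc = params["tau_exc"], tau_inh = params["tau_inh"];
  const double i_ex_e = params["i_ex_e"], i_ex_i = params["i_ex_i"];
  const double circ = params["circumference"], sigma = params["sigma_pc"],
               a_c = params["a_c"], speed = params["speed"];
  const std::vector<double> c_ca3 = as_vec(params["centers_ca3"]);
  const std::vector<double> c_e = as_vec(params["centers_e"]);
  const std::vector<double> s_e = as_vec(params["offsets_e"]);
  const double eta_hebb = params["eta_hebb"], eta_homeo = params["eta_homeo"],
               theta_homeo = params["theta_homeo"], hebb_w_max = params["hebb_w_max"],
               tau_hebb = params["tau_hebb"];
  const double idip_eta = params["idip_eta"], theta_in = params["idip_theta_in"],
               tau_idip = params["idip_tau"];

  double t0 = state["t"];
  std::vector<double> v_c = as_vec(state["v_ca3"]), v_e = as_vec(state["v_e"]),
                      v_i = as_vec(state["v_i"]);
  std::vector<double> ref_c = as_vec(state["ref_ca3"]), ref_e = as_vec(state["ref_e"]),
                      ref_i = as_vec(state["ref_i"]);
  NumericMatrix w_ff = clone(as<NumericMatrix>(state["w_ff"]));   // 100 x 10
  NumericMatrix w_ie = clone(as<NumericMatrix>(state["w_ie"]));   // 20 x 100
  NumericMatrix w_ei = clone(as<NumericMatrix>(state["w_ei"]));   // 100 x 20
  std::vector<double> g_ff = as_vec(state["g_ff"]), g_ei = as_vec(state["g_ei"]),
                      g_ie = as_vec(state["g_ie"]);
  std::vector<double> y = as_vec(state["y"]);
  std::vector<double> x_ca3 = as_vec(state["x_ca3"]), x_e = as_vec(state["x_e"]);
  std::vector<char> sp_c = as_charvec(state["sp_ca3"]), sp_e = as_charvec(state["sp_e"]),
                    sp_i = as_charvec(state["sp_i"]);

  const int n_c = v_c.size(), n_e = v_e.size(), n_i = v_i.size();
  const int n_steps = (int)std::lround(duration_ms / dt);

  std::vector<char> clamp_e(n_e, 0), noclamp(std::max(n_c, n_i), 0);
  if (silence.size() == n_e) {
    for (int i = 0; i < n_e; ++i) clamp_e[i] = silence[i] ? 1 : 0;
  } else if (silence.size() != 0) {
    stop("silencing mask must have one entry per CA1 excitatory neuron");
  }

  std::vector<char> now_c(n_c), now_e(n_e), now_i(n_i);
  std::vector<double> i_c(n_c), i_e(n_e), i_i(n_i, i_ex_i);
  std::vector<double> zeros_c(n_c, 0.0), zeros_e(n_e, 0.0), zeros_i(n_i, 0.0);

  SpikeLog log;
  log.pop.reserve(1 << 16);
  std::vector<double> y_spk_sum(n_i, 0.0);
  std::vector<int> y_spk_n(n_i, 0);
  std::vector<double> trace_t, trace_wei, trace_y;

  const double two_sig2 = 2.0 * sigma * sigma;
  auto tuning = [&](double p, double c) {
    double d = std::fabs(p - c);
    d = std::min(d, circ - d);  // circular distance on the annulus
    return std::exp(-d * d / two_sig2);
  };

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = t0 + (step + 1) * dt;
    const double pos = wrap_pos(speed * t_now, circ);

    decay(g_ff, dt, tau_exc); decay(g_ie, dt, tau_exc); decay(g_ei, dt, tau_inh);
    deliver(g_ff, w_ff, sp_c, g_bar);
    deliver(g_ie, w_ie, sp_e, g_bar);
    deliver(g_ei, w_ei, sp_i, g_bar);

    for (int k = 0; k < n_c; ++k) i_c[k] = a_c * tuning(pos, c_ca3[k]);
    for (int j = 0; j < n_e; ++j)
      i_e[j] = a_c * (tuning(pos, c_e[j]) + s_e[j]) + i_ex_e;

    lif_step(v_c, ref_c, noclamp, zeros_c.data(), zeros_c.data(), i_c.data(),
             now_c, v_rest, theta_m, r_m, tau_m, t_ref, v_rev_e, v_rev_i, dt);
    lif_step(v_e, ref_e, clamp_e, g_ff.data(), g_ei.data(), i_e.data(),
             now_e, v_rest, theta_m, r_m, tau_m, t_ref, v_rev_e, v_rev_i, dt);
    lif_step(v_i, ref_i, noclamp, g_ie.data(), zeros_i.data(), i_i.data(),
             now_i, v_rest, theta_m, r_m, tau_m, t_ref, v_rev_e, v_rev_i, dt);

    // traces
    for (int i = 0; i < n_i; ++i) y[i] += dt * (-y[i] / tau_idip + g_ie[i]);
    {
      const double f = 1.0 - dt / tau_hebb;
      for (int k = 0; k < n_c; ++k) { x_ca3[k] *= f; if (now_c[k]) x_ca3[k] += 1.0; }
      for (int j = 0; j < n_e; ++j) { x_e[j] *= f; if (now_e[j]) x_e[j] += 1.0; }
    }

    if (hebb_on) {
      for (int j = 0; j < n_e; ++j) {
        double rowsum = 0;
        for (int k = 0; k < n_c; ++k) rowsum += w_ff(j, k);
        const double homeo = eta_homeo * (rowsum - theta_homeo);
        for (int k = 0; k < n_c; ++k) {
          double w = w_ff(j, k);
          const double hb = eta_hebb * (hebb_w_max - w);
          w += dt * (hb * (x_e[j] * x_ca3[k]) - homeo);
          w_ff(j, k) = std::max(w, 0.0);
        }
      }
    }
    if (idip_on) {
      for (int i = 0; i < n_i; ++i) {
        if (!now_i[i]) continue;
        const double d = idip_eta * (y[i] - theta_in);
        for (int j = 0; j < n_e; ++j)
          w_ei(j, i) = std::max(w_ei(j, i) + d, 0.0);
      }
    }

    for (int k = 0; k < n_c; ++k) if (now_c[k]) log.add(0, k, t_now);
    for (int j = 0; j < n_e; ++j) if (now_e[j]) log.add(1, j, t_now);
    for (int i = 0; i < n_i; ++i) {
      if (now_i[i]) {
        log.add(2, i, t_now);
        if (t_now >= record_from_ms) { y_spk_sum[i] += y[i]; y_spk_n[i]++; }
      }
    }
    if (sample_every_ms > 0 &&
        ((step + 1) % (int)std::lround(sample_every_ms / dt)) == 0) {
      double ws = 0, ys = 0;
      for (int j = 0; j < n_e; ++j) for (int i = 0; i < n_i; ++i) ws += w_ei(j, i);
      for (int i = 0; i < n_i; ++i) ys += y[i];
      trace_t.push_back(t_now);
      trace_wei.push_back(ws / (double)(n_e * n_i));
      trace_y.push_back(ys / n_i);
    }

    std::swap(sp_c, now_c); std::swap(sp_e, now_e); std::swap(sp_i, now_i);
  }

  List new_state = List::create(
    _["t"] = t0 + n_steps * dt,
    _["v_ca3"] = v_c, _["v_e"] = v_e, _["v_i"] = v_i,
    _["ref_ca3"] = ref_c, _["ref_e"] = ref_e, _["ref_i"] = ref_i,
    _["w_ff"] = w_ff, _["w_ie"] = w_ie, _["w_ei"] = w_ei,
    _["g_ff"] = g_ff, _["g_ei"] = g_ei, _["g_ie"] = g_ie,
    _["y"] = y, _["x_ca3"] = x_ca3, _["x_e"] = x_e,
    _["sp_ca3"] = LogicalVector(sp_c.begin(), sp_c.end()),
    _["sp_e"] = LogicalVector(sp_e.begin(), sp_e.end()),
    _["sp_i"] = LogicalVector(sp_i.begin(), sp_i.end()));

  return List::create(
    _["state"] = new_state,
    _["spike_pop"] = IntegerVector(log.pop.begin(), log.pop.end()),
    _["spike_id"] = IntegerVector(log.id.begin(), log.id.end()),
    _["spike_t"] = NumericVector(log.t.begin(), log.t.end()),
    _["y_spike_sum"] = NumericVector(y_spk_sum.begin(), y_spk_sum.end()),
    _["y_spike_n"] = IntegerVector(y_spk_n.begin(), y_spk_n.end()),
    _["trace_t"] = NumericVector(trace_t.begin(), trace_t.end()),
    _["trace_w_ei"] = NumericVector(trace_wei.begin(), trace_wei.end()),
    _["trace_y"] = NumericVector(trace_y.begin(), trace_y.end()));
}
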