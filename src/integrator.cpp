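// Fixed-step integrator for the reduced laminar column.
//
// Units: mV, ms, uS, nF, nA. Membrane update uses exponential Euler on the
// linearized membrane equation; gating variables use exponential Euler on
// their (voltage-frozen) relaxation; synaptic conductances are pairs of
// exactly-decayed exponential states (dual-exponential kinetics).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int N_REC = 4; // AMPA, NMDA, GABA_A, GABA_B

// Traub/Destexhe-style rate functions for fast Na/K spiking currents.
static inline double safe_exprel(double x) {
  // x / (exp(x) - 1), stable near 0
  if (std::fabs(x) < 1e-6) return 1.0 - x / 2.0;
  return x / (std::exp(x) - 1.0);
}

// [[Rcpp::export]]
List integrate_cpp(List pars) {
  // compartment parameters
  NumericVector C   = pars["C"];
  NumericVector gL  = pars["gL"];
  NumericVector EL  = pars["EL"];
  NumericVector gNa = pars["gNa"];
  NumericVector gK  = pars["gK"];
  NumericVector gSlow = pars["gSlow"]; // slow depolarizing (calcium-like)
  NumericVector slow_par = pars["slow_par"]; // E, tau(ms), vmid, k
  const int n_comp = C.size();

  // axial edges: from (soma side, lower) -> to (distal side, upper)
  IntegerVector edge_a = pars["edge_a"], edge_b = pars["edge_b"];
  NumericVector edge_g = pars["edge_g"], edge_len = pars["edge_len"];
  IntegerVector edge_layer = pars["edge_layer"]; // 0 none, 1 L2, 2 L5
  const int n_edge = edge_a.size();

  // synaptic kinetics per compartment x receptor (flattened comp*4 + r)
  NumericVector dec_r = pars["decay_rise"], dec_d = pars["decay_fall"];
  NumericVector syn_norm = pars["syn_norm"];
  NumericVector Esyn = pars["Esyn"]; // length 4
  const int nmda_idx = as<int>(pars["nmda_idx"]); // 0-based receptor index
  NumericVector nmda_mg = pars["nmda_mg"]; // per-comp: 1 = Mg block active

  // exogenous events, sorted by step
  IntegerVector ev_step = pars["ev_step"], ev_state = pars["ev_state"];
  NumericVector ev_w = pars["ev_w"];
  const int n_ev = ev_step.size();

  // spiking cells and local connectivity (CSR over cells)
  IntegerVector cell_soma = pars["cell_soma"]; // comp index per cell
  IntegerVector conn_ptr = pars["conn_ptr"];   // length n_cell+1
  IntegerVector conn_target = pars["conn_target"]; // state index comp*4+r
  NumericVector conn_w = pars["conn_w"];
  IntegerVector conn_delay = pars["conn_delay"]; // in steps, >= 0
  const int n_cell = cell_soma.size();

  const int n_steps = as<int>(pars["n_steps"]);
  const double dt = as<double>(pars["dt"]);
  const double vbound = as<double>(pars["vbound"]);
  const double vthresh = as<double>(pars["spike_threshold"]);
  const int refr_steps = as<int>(pars["refractory_steps"]);

  IntegerVector rec_v_comp = pars["record_v"];     // compartments to record V
  IntegerVector rec_g_state = pars["record_g"];    // syn states to record g

  // ---- state ----
  std::vector<double> V(n_comp), m(n_comp, 0.0), h(n_comp, 0.0), n(n_comp, 0.0),
      q(n_comp, 0.0);
  std::vector<double> A(n_comp * N_REC, 0.0), B(n_comp * N_REC, 0.0);
  const double VT = -55.0, ENa = 50.0, EK = -90.0;
  const double Eslow = slow_par[0], tau_slow = slow_par[1],
               vmid_slow = slow_par[2], k_slow = slow_par[3];

  bool has_init = pars.containsElementNamed("init") &&
    !Rf_isNull(pars["init"]);
  if (has_init) {
    List init = pars["init"];
    NumericVector V0 = init["V"], m0 = init["m"], h0 = init["h"],
        n0 = init["n"], q0 = init["q"];
    for (int i = 0; i < n_comp; ++i) {
      V[i] = V0[i]; m[i] = m0[i]; h[i] = h0[i]; n[i] = n0[i]; q[i] = q0[i];
    }
  }
  if (!has_init) {
    for (int i = 0; i < n_comp; ++i) {
      V[i] = EL[i];
      double v2 = V[i] - VT;
      double am = 0.32 * 4.0 * safe_exprel((13.0 - v2) / 4.0);
      double bm = 0.28 * 5.0 * safe_exprel((v2 - 40.0) / 5.0);
      double ah = 0.128 * std::exp((17.0 - v2) / 18.0);
      double bh = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
      double an = 0.032 * 5.0 * safe_exprel((15.0 - v2) / 5.0);
      double bn = 0.5 * std::exp((10.0 - v2) / 40.0);
      m[i] = am / (am + bm);
      h[i] = ah / (ah + bh);
      n[i] = an / (an + bn);
      q[i] = 1.0 / (1.0 + std::exp(-(V[i] - vmid_slow) / k_slow));
    }
  }

  // delayed-delivery ring buffer
  int max_delay = 0;
  for (int i = 0; i < conn_delay.size(); ++i)
    if (conn_delay[i] > max_delay) max_delay = conn_delay[i];
  const int ring_n = max_delay + 2;
  std::vector<std::vector<std::pair<int, double> > > ring(ring_n);

  std::vector<int> last_spike(n_cell, -1000000);
  std::vector<bool> above(n_cell, false);

  // ---- output ----
  NumericVector dip_l2(n_steps + 1), dip_l5(n_steps + 1);
  std::vector<double> spike_t;
  std::vector<int> spike_cell;
  NumericMatrix v_out(rec_v_comp.size() > 0 ? n_steps + 1 : 0, rec_v_comp.size());
  NumericMatrix g_out(rec_g_state.size() > 0 ? n_steps + 1 : 0, rec_g_state.size());

  // dipole at t=0 (uniform rest: zero unless EL differs between coupled comps)
  for (int e = 0; e < n_edge; ++e) {
    double d = edge_g[e] * (V[edge_a[e]] - V[edge_b[e]]) * edge_len[e];
    if (edge_layer[e] == 1) dip_l2[0] += d;
    else if (edge_layer[e] == 2) dip_l5[0] += d;
  }
  for (int k = 0; k < rec_v_comp.size(); ++k) v_out(0, k) = V[rec_v_comp[k]];
  for (int k = 0; k < rec_g_state.size(); ++k) g_out(0, k) = 0.0;

  std::vector<double> Vnew(n_comp), scratch_g_(n_comp), scratch_i_(n_comp);
  int ev_ptr = 0;

  for (int step = 0; step < n_steps; ++step) {
    // deliver exogenous events scheduled for this step
    while (ev_ptr < n_ev && ev_step[ev_ptr] == step) {
      A[ev_state[ev_ptr]] += ev_w[ev_ptr];
      B[ev_state[ev_ptr]] += ev_w[ev_ptr];
      ++ev_ptr;
    }
    // deliver delayed local events
    std::vector<std::pair<int, double> > &bucket = ring[step % ring_n];
    for (size_t j = 0; j < bucket.size(); ++j) {
      A[bucket[j].first] += bucket[j].second;
      B[bucket[j].first] += bucket[j].second;
    }
    bucket.clear();

    // membrane update
    for (int i = 0; i < n_comp; ++i) {
      double gtot = gL[i], itot = gL[i] * EL[i];
      // synapses
      for (int r = 0; r < N_REC; ++r) {
        int s = i * N_REC + r;
        double g = syn_norm[s] * (B[s] - A[s]);
        if (g != 0.0) {
          if (r == nmda_idx && nmda_mg[i] != 0.0) // Jahr-Stevens, 1 mM Mg
            g *= 1.0 / (1.0 + 0.28 * std::exp(-0.062 * V[i]));
          gtot += g;
          itot += g * Esyn[r];
        }
      }
      // spiking conductances
      if (gNa[i] > 0.0) {
        double gna = gNa[i] * m[i] * m[i] * m[i] * h[i];
        double gk = gK[i] * n[i] * n[i] * n[i] * n[i];
        gtot += gna + gk;
        itot += gna * ENa + gk * EK;
      }
      if (gSlow[i] > 0.0) {
        double gs = gSlow[i] * q[i];
        gtot += gs;
        itot += gs * Eslow;
      }
      scratch_g_[i] = gtot;
      scratch_i_[i] = itot;
    }
    // axial coupling contributions (linear in neighbor V at current step)
    for (int e = 0; e < n_edge; ++e) {
      int a = edge_a[e], b = edge_b[e];
      scratch_g_[a] += edge_g[e];
      scratch_i_[a] += edge_g[e] * V[b];
      scratch_g_[b] += edge_g[e];
      scratch_i_[b] += edge_g[e] * V[a];
    }
    double t_next = (step + 1) * dt;
    for (int i = 0; i < n_comp; ++i) {
      double gtot = scratch_g_[i], itot = scratch_i_[i];
      double vinf = itot / gtot;
      Vnew[i] = vinf + (V[i] - vinf) * std::exp(-dt * gtot / C[i]);
      if (!(std::fabs(Vnew[i]) <= vbound)) {
        stop("integration diverged at t = %f ms in compartment %d (V = %f mV)",
             t_next, i + 1, Vnew[i]);
      }
    }
    // gating updates (use pre-update V)
    for (int i = 0; i < n_comp; ++i) {
      if (gNa[i] > 0.0) {
        double v2 = V[i] - VT;
        double am = 0.32 * 4.0 * safe_exprel((13.0 - v2) / 4.0);
        double bm = 0.28 * 5.0 * safe_exprel((v2 - 40.0) / 5.0);
        double ah = 0.128 * std::exp((17.0 - v2) / 18.0);
        double bh = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
        double an = 0.032 * 5.0 * safe_exprel((15.0 - v2) / 5.0);
        double bn = 0.5 * std::exp((10.0 - v2) / 40.0);
        double s, inf;
        s = am + bm; inf = am / s; m[i] = inf + (m[i] - inf) * std::exp(-dt * s);
        s = ah + bh; inf = ah / s; h[i] = inf + (h[i] - inf) * std::exp(-dt * s);
        s = an + bn; inf = an / s; n[i] = inf + (n[i] - inf) * std::exp(-dt * s);
      }
      if (gSlow[i] > 0.0) {
        double inf = 1.0 / (1.0 + std::exp(-(V[i] - vmid_slow) / k_slow));
        q[i] = inf + (q[i] - inf) * std::exp(-dt / tau_slow);
      }
    }
    for (int i = 0; i < n_comp; ++i) V[i] = Vnew[i];

    // spike detection and local synaptic transmission
    for (int c = 0; c < n_cell; ++c) {
      double v = V[cell_soma[c]];
      if (!above[c] && v >= vthresh) {
        above[c] = true;
        if (step - last_spike[c] >= refr_steps) {
          last_spike[c] = step;
          spike_t.push_back(t_next);
          spike_cell.push_back(c + 1);
          for (int j = conn_ptr[c]; j < conn_ptr[c + 1]; ++j) {
            int deliver = (step + conn_delay[j]) % ring_n;
            ring[deliver].push_back(std::make_pair(conn_target[j], conn_w[j]));
          }
        }
      } else if (above[c] && v < vthresh) {
        above[c] = false;
      }
    }

    // synaptic state decay to end of step
    for (int s = 0; s < n_comp * N_REC; ++s) {
      A[s] *= dec_r[s];
      B[s] *= dec_d[s];
    }

    // record
    for (int e = 0; e < n_edge; ++e) {
      double d = edge_g[e] * (V[edge_a[e]] - V[edge_b[e]]) * edge_len[e];
      if (edge_layer[e] == 1) dip_l2[step + 1] += d;
      else if (edge_layer[e] == 2) dip_l5[step + 1] += d;
    }
    for (int k = 0; k < rec_v_comp.size(); ++k)
      v_out(step + 1, k) = V[rec_v_comp[k]];
    for (int k = 0; k < rec_g_state.size(); ++k) {
      int s = rec_g_state[k];
      g_out(step + 1, k) = syn_norm[s] * (B[s] - A[s]);
    }
  }

  return List::create(
      _["dipole_l2"] = dip_l2, _["dipole_l5"] = dip_l5,
      _["spike_time"] = NumericVector(spike_t.begin(), spike_t.end()),
      _["spike_cell"] = IntegerVector(spike_cell.begin(), spike_cell.end()),
      _["v"] = v_out, _["g"] = g_out,
      _["state"] = List::create(
          _["V"] = NumericVector(V.begin(), V.end()),
          _["m"] = NumericVector(m.begin(), m.end()),
          _["h"] = NumericVector(h.begin(), h.end()),
          _["n"] = NumericVector(n.begin(), n.end()),
          _["q"] = NumericVector(q.begin(), q.end())));
}
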