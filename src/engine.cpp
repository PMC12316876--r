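#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "traces.h"

using namespace Rcpp;
using bcpnnet::TraceSet;

// Clock-driven simulation core.
//
// Neurons: AdEx with spike-triggered adaptation and an intrinsic
// excitability (bias) current; exponential-Euler for the linear part,
// forward evaluation of the exponential upstroke with an argument clamp.
// Synapses: conductance-based AMPA/NMDA/GABA with exponential decay;
// glutamatergic connections carry Tsodyks-Markram augmentation/depression
// state updated lazily (exactly) at presynaptic deliveries.  Associative
// (between-network) connections additionally carry full BCPNN trace sets
// for a fast (AMPA) and slow (NMDA) component, propagated analytically
// between the events that touch them (pre deliveries, post spikes, global
// syncs); their weights are recomputed from the probability traces at
// every delivery, so the conductance always uses the current weight.
// Negative weights are delivered as positive conductance on the GABA
// channel.  Spikes travel through a per-step ring buffer keyed by arrival
// step, which reproduces each connection's delay exactly (quantized to dt).

enum ConnType { WITHIN = 0, ASSOC = 1, PYR_BASK = 2, BASK_PYR = 3 };

struct EngineParams {
  double dt;
  // neuron
  double C_m, g_L, E_L, Delta_T, V_t, V_r, tau_ref, b, tau_Iw;
  // receptors
  double tau_a, tau_n, tau_g, E_a, E_n, E_g;
  // short-term plasticity
  double U, tau_A, tau_D;
  // bcpnn
  double tau_z_a, tau_z_n, tau_e, tau_p, f_max_ms, eps, t_spike;
  double w_gain_a, w_gain_n, beta_gain, kappa_normal;
  int bias_comp;  // 0 = fast/AMPA component, 1 = slow/NMDA component
  // stimulation
  double r_bg_ms, g_bg, r_stim_ms, g_stim;
  // scale-profile gains applied to learned weights
  double gain_assoc;
};

class Engine {
public:
  EngineParams p;
  int n;
  std::vector<uint8_t> is_pyr;
  std::vector<double> V, Iw, refr, Ibeta;
  std::vector<double> gA, gN, gG;

  // connections
  std::vector<int> pre, post, dstep;
  std::vector<uint8_t> type, severed;
  std::vector<double> w_a, w_n;          // static / frozen weights (nS)
  std::vector<double> su, sx, st;        // TM state
  std::vector<TraceSet> tr_a, tr_n;      // BCPNN traces (ASSOC only)
  std::vector<double> t_tr;
  std::vector<int> out_start, out_idx;   // CSR by presynaptic cell
  std::vector<int> in_start, in_idx;     // CSR by postsynaptic cell (ASSOC)

  // per-cell traces (bias), both components
  std::vector<double> cZa, cEa, cPa, cZn, cEn, cPn, t_cell;

  // ring buffer
  std::vector<std::vector<int> > ring;
  int ring_pos;

  // stimulation / noise
  std::vector<uint8_t> stim_on;
  std::vector<double> nx_e, nx_i, nx_s;
  std::vector<int> stim_fresh;

  double kappa;        // current associative learning-rate factor
  double t_now;
  long long step_no;
  bool record;
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  std::vector<int> cnt;

  double dZa, dZn, dec_a, dec_n, dec_g, dec_w, dec_m, tau_m, cutoff;

  Engine(List par, List cells, List conns, List init) {
    List q = par;
    p.dt = q["dt"];
    p.C_m = q["C_m"]; p.g_L = q["g_L"]; p.E_L = q["E_L"];
    p.Delta_T = q["Delta_T"]; p.V_t = q["V_t"]; p.V_r = q["V_r"];
    p.tau_ref = q["tau_ref"]; p.b = q["b"]; p.tau_Iw = q["tau_Iw"];
    p.tau_a = q["tau_a"]; p.tau_n = q["tau_n"]; p.tau_g = q["tau_g"];
    p.E_a = q["E_a"]; p.E_n = q["E_n"]; p.E_g = q["E_g"];
    p.U = q["U"]; p.tau_A = q["tau_A"]; p.tau_D = q["tau_D"];
    p.tau_z_a = q["tau_z_a"]; p.tau_z_n = q["tau_z_n"];
    p.tau_e = q["tau_e"]; p.tau_p = q["tau_p"];
    p.f_max_ms = q["f_max_ms"]; p.eps = q["eps"]; p.t_spike = q["t_spike"];
    p.w_gain_a = q["w_gain_a"]; p.w_gain_n = q["w_gain_n"];
    p.beta_gain = q["beta_gain"]; p.kappa_normal = q["kappa_normal"];
    p.bias_comp = q["bias_comp"];
    p.r_bg_ms = q["r_bg_ms"]; p.g_bg = q["g_bg"];
    p.r_stim_ms = q["r_stim_ms"]; p.g_stim = q["g_stim"];
    p.gain_assoc = q["gain_assoc"];

    IntegerVector ip = cells["is_pyr"];
    n = ip.size();
    is_pyr.assign(ip.begin(), ip.end());
    V.assign(n, p.E_L); Iw.assign(n, 0.0); refr.assign(n, 0.0);
    Ibeta.assign(n, 0.0);
    gA.assign(n, 0.0); gN.assign(n, 0.0); gG.assign(n, 0.0);

    IntegerVector cpre = conns["pre"], cpost = conns["post"],
        cd = conns["delay_steps"], ct = conns["type"];
    NumericVector cwa = conns["w_a"], cwn = conns["w_n"];
    int m = cpre.size();
    pre.assign(cpre.begin(), cpre.end());
    post.assign(cpost.begin(), cpost.end());
    dstep.assign(cd.begin(), cd.end());
    type.assign(ct.begin(), ct.end());
    severed.assign(m, 0);
    w_a.assign(cwa.begin(), cwa.end());
    w_n.assign(cwn.begin(), cwn.end());
    su.assign(m, p.U); sx.assign(m, 1.0); st.assign(m, 0.0);
    t_tr.assign(m, 0.0);
    tr_a.assign(m, bcpnnet::trace_rest(p.eps, p.eps, p.eps, p.eps * p.eps));
    tr_n.assign(m, bcpnnet::trace_rest(p.eps, p.eps, p.eps, p.eps * p.eps));

    NumericMatrix cinit = init["cell_traces"];  // n x 6: Za Ea Pa Zn En Pn
    cZa.assign(n, p.eps); cEa.assign(n, p.eps); cPa.assign(n, p.eps);
    cZn.assign(n, p.eps); cEn.assign(n, p.eps); cPn.assign(n, p.eps);
    t_cell.assign(n, 0.0);
    for (int i = 0; i < n; ++i) {
      if (!is_pyr[i]) continue;
      cZa[i] = cinit(i, 0); cEa[i] = cinit(i, 1); cPa[i] = cinit(i, 2);
      cZn[i] = cinit(i, 3); cEn[i] = cinit(i, 4); cPn[i] = cinit(i, 5);
      double Pb = p.bias_comp == 0 ? cPa[i] : cPn[i];
      Ibeta[i] = p.beta_gain * std::log(Pb);
    }
    // associative trace init: cell P marginals, independent co-trace
    for (int s = 0; s < m; ++s) {
      if (type[s] != ASSOC) continue;
      int a = pre[s], bpost = post[s];
      tr_a[s].Pi = cPa[a]; tr_a[s].Pj = cPa[bpost];
      tr_a[s].Pij = cPa[a] * cPa[bpost];
      tr_n[s].Pi = cPn[a]; tr_n[s].Pj = cPn[bpost];
      tr_n[s].Pij = cPn[a] * cPn[bpost];
    }

    // CSR adjacency
    out_start.assign(n + 1, 0); in_start.assign(n + 1, 0);
    for (int s = 0; s < m; ++s) out_start[pre[s] + 1]++;
    for (int i = 0; i < n; ++i) out_start[i + 1] += out_start[i];
    out_idx.assign(m, 0);
    { std::vector<int> fill(out_start.begin(), out_start.end() - 1);
      for (int s = 0; s < m; ++s) out_idx[fill[pre[s]]++] = s; }
    int mp = 0;
    for (int s = 0; s < m; ++s) if (type[s] == ASSOC) mp++;
    for (int s = 0; s < m; ++s) if (type[s] == ASSOC) in_start[post[s] + 1]++;
    for (int i = 0; i < n; ++i) in_start[i + 1] += in_start[i];
    in_idx.assign(mp, 0);
    { std::vector<int> fill(in_start.begin(), in_start.end() - 1);
      for (int s = 0; s < m; ++s)
        if (type[s] == ASSOC) in_idx[fill[post[s]]++] = s; }

    int maxd = 2;
    for (int s = 0; s < m; ++s) maxd = std::max(maxd, dstep[s]);
    ring.assign(maxd + 2, std::vector<int>());
    ring_pos = 0;

    stim_on.assign(n, 0);
    nx_e.assign(n, R_PosInf); nx_i.assign(n, R_PosInf);
    nx_s.assign(n, R_PosInf);

    kappa = p.kappa_normal;
    t_now = 0.0; step_no = 0; record = false;
    cnt.assign(n, 0);

    dZa = bcpnnet::z_jump(p.f_max_ms, p.t_spike, p.tau_z_a);
    dZn = bcpnnet::z_jump(p.f_max_ms, p.t_spike, p.tau_z_n);
    dec_a = std::exp(-p.dt / p.tau_a);
    dec_n = std::exp(-p.dt / p.tau_n);
    dec_g = std::exp(-p.dt / p.tau_g);
    dec_w = std::exp(-p.dt / p.tau_Iw);
    tau_m = p.C_m / p.g_L;
    dec_m = std::exp(-p.dt / tau_m);
    cutoff = p.V_t + 10.0 * p.Delta_T;
  }

  inline void prop_conn(int s, double t) {
    double dt = t - t_tr[s];
    if (dt > 0) {
      double lpk = kappa / p.tau_p;
      bcpnnet::prop_set(tr_a[s], dt, 1.0 / p.tau_z_a, 1.0 / p.tau_e, lpk, p.eps);
      bcpnnet::prop_set(tr_n[s], dt, 1.0 / p.tau_z_n, 1.0 / p.tau_e, lpk, p.eps);
      t_tr[s] = t;
    }
  }

  inline void prop_cell(int i, double t) {
    double dt = t - t_cell[i];
    if (dt > 0) {
      double lpk = p.kappa_normal / p.tau_p;
      bcpnnet::prop_chain(cZa[i], cEa[i], cPa[i], dt,
                          1.0 / p.tau_z_a, 1.0 / p.tau_e, lpk, p.eps);
      bcpnnet::prop_chain(cZn[i], cEn[i], cPn[i], dt,
                          1.0 / p.tau_z_n, 1.0 / p.tau_e, lpk, p.eps);
      t_cell[i] = t;
    }
  }

  inline void stp_update(int s, double t) {
    double dt = t - st[s];
    su[s] = p.U + (su[s] - p.U) * std::exp(-dt / p.tau_A);
    sx[s] = 1.0 + (sx[s] - 1.0) * std::exp(-dt / p.tau_D);
    su[s] = su[s] + p.U * (1.0 - su[s]);
    st[s] = t;
  }

  inline void deliver(int s, double t) {
    if (severed[s]) return;
    int j = post[s];
    switch (type[s]) {
    case PYR_BASK: gA[j] += w_a[s]; break;
    case BASK_PYR: gG[j] += -w_a[s]; break;  // w_a stored negative
    case WITHIN: {
      stp_update(s, t);
      double gain = su[s] * sx[s];
      sx[s] -= gain;
      double qa = gain * w_a[s], qn = gain * w_n[s];
      if (qa >= 0) gA[j] += qa; else gG[j] += -qa;
      if (qn >= 0) gN[j] += qn; else gG[j] += -qn;
      break; }
    case ASSOC: {
      stp_update(s, t);
      double gain = su[s] * sx[s];
      sx[s] -= gain;
      prop_conn(s, t);
      tr_a[s].Zi += dZa; tr_n[s].Zi += dZn;
      double wa = p.gain_assoc * bcpnnet::bcpnn_weight(tr_a[s], p.w_gain_a);
      double wn = p.gain_assoc * bcpnnet::bcpnn_weight(tr_n[s], p.w_gain_n);
      double qa = gain * wa, qn = gain * wn;
      if (qa >= 0) gA[j] += qa; else gG[j] += -qa;
      if (qn >= 0) gN[j] += qn; else gG[j] += -qn;
      break; }
    }
  }

  void sync_traces() {
    int m = pre.size();
    for (int s = 0; s < m; ++s)
      if (type[s] == ASSOC && !severed[s]) prop_conn(s, t_now);
    for (int i = 0; i < n; ++i) {
      if (!is_pyr[i]) continue;
      prop_cell(i, t_now);
      double Pb = p.bias_comp == 0 ? cPa[i] : cPn[i];
      Ibeta[i] = p.beta_gain * std::log(Pb);
    }
  }

  void set_kappa(double k) { sync_traces(); kappa = k; }

  void set_stim(IntegerVector cells) {
    std::fill(stim_on.begin(), stim_on.end(), 0);
    std::fill(nx_s.begin(), nx_s.end(), R_PosInf);
    stim_fresh.assign(cells.begin(), cells.end());
  }

  void advance(double t_until) {
    GetRNGstate();
    if (!stim_fresh.empty() || true) {
      for (size_t k = 0; k < stim_fresh.size(); ++k) {
        int i = stim_fresh[k];
        stim_on[i] = 1;
        nx_s[i] = t_now + R::rexp(1.0 / p.r_stim_ms);
      }
      stim_fresh.clear();
    }
    // lazy-init background noise event times
    if (p.r_bg_ms > 0) {
      for (int i = 0; i < n; ++i) {
        if (!is_pyr[i]) continue;
        if (!R_FINITE(nx_e[i])) nx_e[i] = t_now + R::rexp(1.0 / p.r_bg_ms);
        if (!R_FINITE(nx_i[i])) nx_i[i] = t_now + R::rexp(1.0 / p.r_bg_ms);
      }
    }
    long long steps = (long long)std::floor((t_until - t_now) / p.dt + 0.5);
    for (long long q = 0; q < steps; ++q) {
      double t = t_now + p.dt;  // end-of-step time; deliveries use it
      // 1. deliveries scheduled for this step
      std::vector<int> &slot = ring[ring_pos];
      for (size_t k = 0; k < slot.size(); ++k) deliver(slot[k], t);
      slot.clear();
      // 2/3. noise, stimulation, membrane update
      for (int i = 0; i < n; ++i) {
        if (is_pyr[i]) {
          if (p.r_bg_ms > 0) {
            while (nx_e[i] <= t) { gA[i] += p.g_bg;
              nx_e[i] += R::rexp(1.0 / p.r_bg_ms); }
            while (nx_i[i] <= t) { gG[i] += p.g_bg;
              nx_i[i] += R::rexp(1.0 / p.r_bg_ms); }
          }
          if (stim_on[i]) {
            while (nx_s[i] <= t) { gA[i] += p.g_stim;
              nx_s[i] += R::rexp(1.0 / p.r_stim_ms); }
          }
        }
        if (refr[i] > 0) {
          refr[i] -= p.dt;
          V[i] = p.V_r;
          Iw[i] *= dec_w;
        } else {
          double v = V[i];
          double Isyn = -(gA[i] * (v - p.E_a) + gN[i] * (v - p.E_n)
                          + gG[i] * (v - p.E_g));
          double ex = (v - p.V_t) / p.Delta_T;
          if (ex > 20.0) ex = 20.0;
          double Itot = p.g_L * p.Delta_T * std::exp(ex)
                        + Ibeta[i] + Isyn - Iw[i];
          double vinf = p.E_L + Itot / p.g_L;
          v = vinf + (v - vinf) * dec_m;
          Iw[i] *= dec_w;
          if (v > cutoff) {
            // spike
            V[i] = p.V_r; refr[i] = p.tau_ref; Iw[i] += p.b;
            cnt[i]++;
            if (record) { sp_t.push_back(t); sp_id.push_back(i); }
            if (is_pyr[i]) {
              prop_cell(i, t);
              cZa[i] += dZa; cZn[i] += dZn;
              double Pb = p.bias_comp == 0 ? cPa[i] : cPn[i];
              Ibeta[i] = p.beta_gain * std::log(Pb);
              for (int k = in_start[i]; k < in_start[i + 1]; ++k) {
                int s = in_idx[k];
                if (severed[s]) continue;
                prop_conn(s, t);
                tr_a[s].Zj += dZa; tr_n[s].Zj += dZn;
              }
            }
            for (int k = out_start[i]; k < out_start[i + 1]; ++k) {
              int s = out_idx[k];
              int slot2 = (ring_pos + dstep[s]) % (int)ring.size();
              ring[slot2].push_back(s);
            }
          } else {
            V[i] = v;
            if (!R_FINITE(v)) {
              PutRNGstate();
              stop("non-finite membrane potential at t = %f (cell %d)", t, i);
            }
          }
        }
        gA[i] *= dec_a; gN[i] *= dec_n; gG[i] *= dec_g;
      }
      ring_pos = (ring_pos + 1) % (int)ring.size();
      t_now = t;
      step_no++;
      if ((step_no & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    }
    PutRNGstate();
  }
};

typedef XPtr<Engine> EngPtr;

// [[Rcpp::export(name = ".cpp_engine_create")]]
SEXP cpp_engine_create(List params, List cells, List conns, List init) {
  Engine *e = new Engine(params, cells, conns, init);
  return EngPtr(e, true);
}

// [[Rcpp::export(name = ".cpp_engine_advance")]]
void cpp_engine_advance(SEXP ep, double t_until) {
  EngPtr e(ep); e->advance(t_until);
}

// [[Rcpp::export(name = ".cpp_engine_set_stim")]]
void cpp_engine_set_stim(SEXP ep, IntegerVector cells) {
  EngPtr e(ep); e->set_stim(cells);
}

// [[Rcpp::export(name = ".cpp_engine_set_kappa")]]
void cpp_engine_set_kappa(SEXP ep, double kappa) {
  EngPtr e(ep); e->set_kappa(kappa);
}

// [[Rcpp::export(name = ".cpp_engine_time")]]
double cpp_engine_time(SEXP ep) { EngPtr e(ep); return e->t_now; }

// [[Rcpp::export(name = ".cpp_engine_counts_reset")]]
void cpp_engine_counts_reset(SEXP ep) {
  EngPtr e(ep); std::fill(e->cnt.begin(), e->cnt.end(), 0);
}

// [[Rcpp::export(name = ".cpp_engine_counts")]]
IntegerVector cpp_engine_counts(SEXP ep) {
  EngPtr e(ep); return wrap(e->cnt);
}

// [[Rcpp::export(name = ".cpp_engine_record")]]
void cpp_engine_record(SEXP ep, bool on) { EngPtr e(ep); e->record = on; }

// [[Rcpp::export(name = ".cpp_engine_spikes")]]
DataFrame cpp_engine_spikes(SEXP ep, bool clear) {
  EngPtr e(ep);
  DataFrame out = DataFrame::create(_["time_ms"] = wrap(e->sp_t),
                                    _["gid"] = wrap(e->sp_id));
  if (clear) { e->sp_t.clear(); e->sp_id.clear(); }
  return out;
}

// [[Rcpp::export(name = ".cpp_engine_voltages")]]
NumericVector cpp_engine_voltages(SEXP ep) {
  EngPtr e(ep); return wrap(e->V);
}

// [[Rcpp::export(name = ".cpp_engine_biases")]]
NumericVector cpp_engine_biases(SEXP ep) {
  EngPtr e(ep); e->sync_traces(); return wrap(e->Ibeta);
}

// Current effective STP state of every connection, relaxed analytically to
// the present time without consuming a spike.
// [[Rcpp::export(name = ".cpp_engine_stp_state")]]
NumericMatrix cpp_engine_stp_state(SEXP ep) {
  EngPtr e(ep);
  int m = e->pre.size();
  NumericMatrix out(m, 2);
  for (int s = 0; s < m; ++s) {
    double dt = e->t_now - e->st[s];
    out(s, 0) = e->p.U + (e->su[s] - e->p.U) * std::exp(-dt / e->p.tau_A);
    out(s, 1) = 1.0 + (e->sx[s] - 1.0) * std::exp(-dt / e->p.tau_D);
  }
  return out;
}

// Full tabular snapshot of the associative (plastic) connections.
// [[Rcpp::export(name = ".cpp_engine_snapshot_assoc")]]
DataFrame cpp_engine_snapshot_assoc(SEXP ep) {
  EngPtr e(ep);
  e->sync_traces();
  int m = e->pre.size(), na = 0;
  for (int s = 0; s < m; ++s) if (e->type[s] == ASSOC) na++;
  IntegerVector rpre(na), rpost(na), rsev(na);
  NumericVector ru(na), rx(na);
  NumericVector pia(na), pja(na), pija(na), wa(na);
  NumericVector pin(na), pjn(na), pijn(na), wn(na);
  int k = 0;
  for (int s = 0; s < m; ++s) {
    if (e->type[s] != ASSOC) continue;
    rpre[k] = e->pre[s]; rpost[k] = e->post[s]; rsev[k] = e->severed[s];
    double dt = e->t_now - e->st[s];
    ru[k] = e->p.U + (e->su[s] - e->p.U) * std::exp(-dt / e->p.tau_A);
    rx[k] = 1.0 + (e->sx[s] - 1.0) * std::exp(-dt / e->p.tau_D);
    pia[k] = e->tr_a[s].Pi; pja[k] = e->tr_a[s].Pj; pija[k] = e->tr_a[s].Pij;
    wa[k] = e->p.gain_assoc * bcpnnet::bcpnn_weight(e->tr_a[s], e->p.w_gain_a);
    pin[k] = e->tr_n[s].Pi; pjn[k] = e->tr_n[s].Pj; pijn[k] = e->tr_n[s].Pij;
    wn[k] = e->p.gain_assoc * bcpnnet::bcpnn_weight(e->tr_n[s], e->p.w_gain_n);
    k++;
  }
  return DataFrame::create(
      _["pre"] = rpre, _["post"] = rpost, _["severed"] = rsev,
      _["u"] = ru, _["x"] = rx,
      _["P_i_ampa"] = pia, _["P_j_ampa"] = pja, _["P_ij_ampa"] = pija,
      _["w_ampa"] = wa,
      _["P_i_nmda"] = pin, _["P_j_nmda"] = pjn, _["P_ij_nmda"] = pijn,
      _["w_nmda"] = wn);
}

// Frozen within-network weights (for the invariance check).
// [[Rcpp::export(name = ".cpp_engine_within_weights")]]
DataFrame cpp_engine_within_weights(SEXP ep) {
  EngPtr e(ep);
  int m = e->pre.size(), nw = 0;
  for (int s = 0; s < m; ++s) if (e->type[s] == WITHIN) nw++;
  IntegerVector rpre(nw), rpost(nw);
  NumericVector wa(nw), wn(nw);
  int k = 0;
  for (int s = 0; s < m; ++s) {
    if (e->type[s] != WITHIN) continue;
    rpre[k] = e->pre[s]; rpost[k] = e->post[s];
    wa[k] = e->w_a[s]; wn[k] = e->w_n[s];
    k++;
  }
  return DataFrame::create(_["pre"] = rpre, _["post"] = rpost,
                           _["w_ampa"] = wa, _["w_nmda"] = wn);
}

// Per-assembly mean effective within-network weight (static weight times
// the instantaneous u*x, AMPA + NMDA summed, averaged over existing
// recurrent connections among the assembly's cells) and mean bias current.
// [[Rcpp::export(name = ".cpp_engine_item_stats")]]
NumericMatrix cpp_engine_item_stats(SEXP ep, List assemblies) {
  EngPtr e(ep);
  e->sync_traces();
  int na = assemblies.size();
  NumericMatrix out(na, 2);
  std::vector<uint8_t> mask(e->n, 0);
  int m = e->pre.size();
  for (int a = 0; a < na; ++a) {
    IntegerVector cells = assemblies[a];
    for (int i = 0; i < cells.size(); ++i) mask[cells[i]] = 1;
    double wsum = 0.0; int wcnt = 0;
    for (int s = 0; s < m; ++s) {
      if (e->type[s] != WITHIN) continue;
      if (!mask[e->pre[s]] || !mask[e->post[s]]) continue;
      double dt = e->t_now - e->st[s];
      double u = e->p.U + (e->su[s] - e->p.U) * std::exp(-dt / e->p.tau_A);
      double x = 1.0 + (e->sx[s] - 1.0) * std::exp(-dt / e->p.tau_D);
      wsum += u * x * (e->w_a[s] + e->w_n[s]);
      wcnt++;
    }
    double bsum = 0.0; int bcnt = 0;
    for (int i = 0; i < cells.size(); ++i) {
      bsum += e->Ibeta[cells[i]]; bcnt++;
    }
    out(a, 0) = wcnt ? wsum / wcnt : NA_REAL;
    out(a, 1) = bcnt ? bsum / bcnt : NA_REAL;
    for (int i = 0; i < cells.size(); ++i) mask[cells[i]] = 0;
  }
  return out;
}

// Sever associative connections whose current weight (either component) is
// negative: they are silenced and excluded from further learning.
// Returns the number of severed connections.
// [[Rcpp::export(name = ".cpp_engine_ablate_neg_assoc")]]
int cpp_engine_ablate_neg_assoc(SEXP ep) {
  EngPtr e(ep);
  e->sync_traces();
  int m = e->pre.size(), k = 0;
  for (int s = 0; s < m; ++s) {
    if (e->type[s] != ASSOC || e->severed[s]) continue;
    double wa = bcpnnet::bcpnn_weight(e->tr_a[s], e->p.w_gain_a);
    double wn = bcpnnet::bcpnn_weight(e->tr_n[s], e->p.w_gain_n);
    if (wa < 0 || wn < 0) { e->severed[s] = 1; k++; }
  }
  return k;
}
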