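#include <Rcpp.h>
#include "traces.h"

using namespace Rcpp;
using bcpnnet::TraceSet;
using bcpnnet::prop_set;
using bcpnnet::prop_chain;
using bcpnnet::z_jump;

// Exact event-free propagation of one full trace set, exposed for the
// R-level plasticity API and its tests.  state: (Zi, Zj, Ei, Ej, Eij,
// Pi, Pj, Pij); times in ms; kappa scales the P stage.
// [[Rcpp::export(name = ".cpp_prop_set")]]
NumericVector cpp_prop_set(NumericVector state, double dt, double tau_z,
                           double tau_e, double tau_p, double kappa,
                           double eps) {
  TraceSet t;
  t.Zi = state[0]; t.Zj = state[1]; t.Ei = state[2]; t.Ej = state[3];
  t.Eij = state[4]; t.Pi = state[5]; t.Pj = state[6]; t.Pij = state[7];
  prop_set(t, dt, 1.0 / tau_z, 1.0 / tau_e, kappa / tau_p, eps);
  return NumericVector::create(t.Zi, t.Zj, t.Ei, t.Ej, t.Eij,
                               t.Pi, t.Pj, t.Pij);
}

// Event-driven trace integration over explicit pre/post spike trains with
// a piecewise-constant kappa schedule.  kappa_t / kappa_v give the start
// times and values of the kappa segments (kappa_t[0] must be <= 0).
// Returns the trace set at time t_end.
// [[Rcpp::export(name = ".cpp_run_traces")]]
NumericVector cpp_run_traces(NumericVector pre, NumericVector post,
                             double t_end, double tau_z, double tau_e,
                             double tau_p, double eps, double f_max_ms,
                             double t_spike, NumericVector kappa_t,
                             NumericVector kappa_v,
                             NumericVector init = NumericVector(0)) {
  const double lz = 1.0 / tau_z, le = 1.0 / tau_e;
  const double dZ = z_jump(f_max_ms, t_spike, tau_z);
  TraceSet t;
  if (init.size() == 8) {
    t.Zi = init[0]; t.Zj = init[1]; t.Ei = init[2]; t.Ej = init[3];
    t.Eij = init[4]; t.Pi = init[5]; t.Pj = init[6]; t.Pij = init[7];
  } else {
    t = bcpnnet::trace_rest(eps, eps, eps, eps * eps);
  }
  double now = 0.0;
  R_xlen_t i = 0, j = 0, k = 0;
  auto kappa_at = [&](double tt) {
    while (k + 1 < kappa_t.size() && kappa_t[k + 1] <= tt) ++k;
    return kappa_v[k];
  };
  auto advance_to = [&](double tt) {
    // split the interval at kappa-segment boundaries
    while (tt > now) {
      double kap = kappa_at(now);
      double seg_end = tt;
      if (k + 1 < kappa_t.size() && kappa_t[k + 1] < tt)
        seg_end = kappa_t[k + 1];
      prop_set(t, seg_end - now, lz, le, kap / tau_p, eps);
      now = seg_end;
    }
  };
  while (i < pre.size() || j < post.size()) {
    double tp = i < pre.size() ? pre[i] : R_PosInf;
    double tq = j < post.size() ? post[j] : R_PosInf;
    double te = std::min(tp, tq);
    if (te >= t_end) break;
    advance_to(te);
    if (tp <= tq) { t.Zi += dZ; ++i; }
    if (tq <= tp) { t.Zj += dZ; ++j; }
  }
  advance_to(t_end);
  return NumericVector::create(t.Zi, t.Zj, t.Ei, t.Ej, t.Eij,
                               t.Pi, t.Pj, t.Pij);
}

// Offline attractor preloading: integrates both trace components of every
// listed connection over prescribed per-cell spike trains (trains[c] =
// sorted spike times of cell c, ms) and returns the terminal probability
// traces and weights.  Presynaptic spikes are shifted by the connection
// delay.  Columns: Pi_a, Pj_a, Pij_a, w_a, Pi_n, Pj_n, Pij_n, w_n.
// [[Rcpp::export(name = ".cpp_preload_connections")]]
NumericMatrix cpp_preload_connections(List trains, IntegerVector pre,
                                      IntegerVector post,
                                      NumericVector delay, double t_end,
                                      double tau_z_a, double tau_z_n,
                                      double tau_e, double tau_p,
                                      double eps, double f_max_ms,
                                      double t_spike, double kappa,
                                      double w_gain_a, double w_gain_n) {
  const R_xlen_t nc = pre.size();
  NumericMatrix out(nc, 8);
  const double lz_a = 1.0 / tau_z_a, lz_n = 1.0 / tau_z_n;
  const double le = 1.0 / tau_e, lpk = kappa / tau_p;
  const double dZ_a = z_jump(f_max_ms, t_spike, tau_z_a);
  const double dZ_n = z_jump(f_max_ms, t_spike, tau_z_n);

  std::vector<NumericVector> tr(trains.size());
  for (R_xlen_t c = 0; c < trains.size(); ++c)
    tr[c] = as<NumericVector>(trains[c]);

  for (R_xlen_t s = 0; s < nc; ++s) {
    const NumericVector &pi = tr[pre[s]];
    const NumericVector &pj = tr[post[s]];
    const double d = delay[s];
    TraceSet ta = bcpnnet::trace_rest(eps, eps, eps, eps * eps);
    TraceSet tn = bcpnnet::trace_rest(eps, eps, eps, eps * eps);
    double now = 0.0;
    R_xlen_t i = 0, j = 0;
    while (i < pi.size() || j < pj.size()) {
      double tp = i < pi.size() ? pi[i] + d : R_PosInf;
      double tq = j < pj.size() ? pj[j] : R_PosInf;
      double te = std::min(tp, tq);
      if (te >= t_end) break;
      if (te > now) {
        prop_set(ta, te - now, lz_a, le, lpk, eps);
        prop_set(tn, te - now, lz_n, le, lpk, eps);
        now = te;
      }
      if (tp <= tq) { ta.Zi += dZ_a; tn.Zi += dZ_n; ++i; }
      if (tq <= tp) { ta.Zj += dZ_a; tn.Zj += dZ_n; ++j; }
    }
    if (t_end > now) {
      prop_set(ta, t_end - now, lz_a, le, lpk, eps);
      prop_set(tn, t_end - now, lz_n, le, lpk, eps);
    }
    out(s, 0) = ta.Pi; out(s, 1) = ta.Pj; out(s, 2) = ta.Pij;
    out(s, 3) = bcpnnet::bcpnn_weight(ta, w_gain_a);
    out(s, 4) = tn.Pi; out(s, 5) = tn.Pj; out(s, 6) = tn.Pij;
    out(s, 7) = bcpnnet::bcpnn_weight(tn, w_gain_n);
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Terminal per-cell (Z, E, P) traces for both components over the cells'
// own spike trains.  Columns: Z_a, E_a, P_a, Z_n, E_n, P_n.
// [[Rcpp::export(name = ".cpp_cell_traces")]]
NumericMatrix cpp_cell_traces(List trains, double t_end, double tau_z_a,
                              double tau_z_n, double tau_e, double tau_p,
                              double eps, double f_max_ms, double t_spike,
                              double kappa) {
  const R_xlen_t n = trains.size();
  NumericMatrix out(n, 6);
  const double lz_a = 1.0 / tau_z_a, lz_n = 1.0 / tau_z_n;
  const double le = 1.0 / tau_e, lpk = kappa / tau_p;
  const double dZ_a = z_jump(f_max_ms, t_spike, tau_z_a);
  const double dZ_n = z_jump(f_max_ms, t_spike, tau_z_n);
  for (R_xlen_t c = 0; c < n; ++c) {
    NumericVector sp = trains[c];
    double Za = eps, Ea = eps, Pa = eps;
    double Zn = eps, En = eps, Pn = eps;
    double now = 0.0;
    for (R_xlen_t i = 0; i < sp.size(); ++i) {
      if (sp[i] >= t_end) break;
      if (sp[i] > now) {
        prop_chain(Za, Ea, Pa, sp[i] - now, lz_a, le, lpk, eps);
        prop_chain(Zn, En, Pn, sp[i] - now, lz_n, le, lpk, eps);
        now = sp[i];
      }
      Za += dZ_a; Zn += dZ_n;
    }
    if (t_end > now) {
      prop_chain(Za, Ea, Pa, t_end - now, lz_a, le, lpk, eps);
      prop_chain(Zn, En, Pn, t_end - now, lz_n, le, lpk, eps);
    }
    out(c, 0) = Za; out(c, 1) = Ea; out(c, 2) = Pa;
    out(c, 3) = Zn; out(c, 4) = En; out(c, 5) = Pn;
  }
  return out;
}
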