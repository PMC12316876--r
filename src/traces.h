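#ifndef BCPNNET_TRACES_H
#define BCPNNET_TRACES_H

#include <cmath>

// Exact propagation of the BCPNN trace cascade between spike events.
//
// Between events the cascade is linear with constant coefficients:
//   tau_Z dZ/dt = -Z + eps
//   tau_E dE/dt =  Z - E           (co trace: Zi*Zj - Eij)
//   tau_P dP/dt =  kappa (E - P)
// so the solution is a sum of exponentials with rates lz (= 1/tau_Z),
// 2*lz (co trace), le (= 1/tau_E) and kappa/tau_P.  Coincident rates are
// nudged apart by a negligible amount rather than handled by limit forms.

namespace bcpnnet {

inline double safe_den(double d) {
  const double tiny = 1e-12;
  if (std::fabs(d) < tiny) return d < 0 ? -tiny : tiny;
  return d;
}

// One pre- or postsynaptic chain (Z, E, P).  lpk = kappa / tau_P.
inline void prop_chain(double &Z, double &E, double &P, double dt,
                       double lz, double le, double lpk, double eps) {
  const double a  = Z - eps;
  const double ez = std::exp(-lz * dt);
  const double ee = std::exp(-le * dt);
  const double c  = le * a / safe_den(le - lz);
  const double d  = E - eps - c;
  if (lpk > 0) {
    const double ep = std::exp(-lpk * dt);
    const double qz = lpk * c / safe_den(lpk - lz);
    const double qe = lpk * d / safe_den(lpk - le);
    P = eps + qz * ez + qe * ee + (P - eps - qz - qe) * ep;
  }
  Z = eps + a * ez;
  E = eps + c * ez + d * ee;
}

// The co-activation chain (Eij <- Zi*Zj, Pij <- Eij).  Does NOT advance
// Zi/Zj (their own chains do); pass their values at interval start.
inline void prop_co(double Zi0, double Zj0, double &Eij, double &Pij,
                    double dt, double lz, double le, double lpk,
                    double eps) {
  const double ai = Zi0 - eps, aj = Zj0 - eps;
  const double ez  = std::exp(-lz * dt);
  const double e2z = ez * ez;
  const double ee  = std::exp(-le * dt);
  const double e2  = eps * eps;
  const double c1  = le * eps * (ai + aj) / safe_den(le - lz);
  const double c2  = le * ai * aj / safe_den(le - 2.0 * lz);
  const double dE  = Eij - e2 - c1 - c2;
  if (lpk > 0) {
    const double ep = std::exp(-lpk * dt);
    const double q1 = lpk * c1 / safe_den(lpk - lz);
    const double q2 = lpk * c2 / safe_den(lpk - 2.0 * lz);
    const double qe = lpk * dE / safe_den(lpk - le);
    Pij = e2 + q1 * ez + q2 * e2z + qe * ee +
          (Pij - e2 - q1 - q2 - qe) * ep;
  }
  Eij = e2 + c1 * ez + c2 * e2z + dE * ee;
}

// Full trace set of one component of one connection.
struct TraceSet {
  double Zi, Zj, Ei, Ej, Eij, Pi, Pj, Pij;
};

inline TraceSet trace_rest(double eps, double Pi, double Pj, double Pij) {
  TraceSet t;
  t.Zi = t.Zj = t.Ei = t.Ej = eps;
  t.Eij = eps * eps;
  t.Pi = Pi; t.Pj = Pj; t.Pij = Pij;
  return t;
}

inline void prop_set(TraceSet &t, double dt, double lz, double le,
                     double lpk, double eps) {
  if (dt <= 0) return;
  prop_co(t.Zi, t.Zj, t.Eij, t.Pij, dt, lz, le, lpk, eps);
  prop_chain(t.Zi, t.Ei, t.Pi, dt, lz, le, lpk, eps);
  prop_chain(t.Zj, t.Ej, t.Pj, dt, lz, le, lpk, eps);
}

// Spike impulse on a Z trace: a rectangular pulse of duration t_spike and
// height 1/(f_max t_spike) lumped into an instantaneous jump of the pulse's
// terminal response (f_max in spikes/ms, t_spike in ms).
inline double z_jump(double f_max_ms, double t_spike, double tau_z) {
  return (1.0 / (f_max_ms * t_spike)) * (1.0 - std::exp(-t_spike / tau_z));
}

// Component parameters of the learning rule in engine units (ms).
struct CompParams {
  double lz;       // 1/tau_Z
  double le;       // 1/tau_E
  double tau_P;    // ms
  double eps;
  double dZ;       // spike-triggered Z increment
  double w_gain;   // nS
};

inline double bcpnn_weight(const TraceSet &t, double w_gain) {
  return w_gain * std::log(t.Pij / (t.Pi * t.Pj));
}

}  // namespace bcpnnet

#endif
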