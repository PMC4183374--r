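#ifndef CASYNAPSE_PLASTICITY_CORE_H
#define CASYNAPSE_PLASTICITY_CORE_H

// Shared event-based propagation of the (calcium, efficacy) pair.
//
// Model: calcium c jumps by C_pre (with delay D after a presynaptic spike)
// or C_post (at a postsynaptic spike) and decays exponentially with time
// constant tau_ca.  The efficacy rho obeys
//   tau_rho * drho/dt = -U'(rho) + gamma_p (1-rho) H(c-theta_p)
//                       - gamma_d rho H(c-theta_d)
//                       + sigma sqrt(tau_rho) sqrt(H(c-theta_d)+H(c-theta_p)) xi
// Between events the calcium trajectory is a known exponential, so the
// interval splits into at most three epochs (above theta_p, between the
// thresholds, below theta_d) whose updates are exact:
//  - above theta_p: Ornstein-Uhlenbeck toward gamma_p/(gamma_p+gamma_d),
//    relaxation rate (gamma_p+gamma_d)/tau_rho, doubled noise variance
//    (both threshold indicators active); the quartic term is negligible
//    there because gamma_p, gamma_d >> 1;
//  - between thresholds: OU toward 0 at rate gamma_d/tau_rho, single noise;
//  - below theta_d: deterministic; identity for the flat potential, the
//    integrated quartic flow for the double well (rho_star = 1/2).
// In flat-potential mode rho is clipped to [0,1] after each stochastic
// epoch (the truncation of the OU process).

#include <algorithm>
#include <cmath>

#include "rng.h"

namespace casyn {

struct PlastParams {
  double Cpre, Cpost, tauCa, thd, thp, gd, gp, sigma, taurho, rhostar, D;
  bool double_well;
};

inline double clip01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// Closed-form relaxation in the bare double well U(rho) = rho^2(1-rho)^2/4
// (barrier at rho_star = 1/2): with x = rho - 1/2,
//   x(t)^2 = 1/4 / (1 + q e^{-t/(2 tau)}),  q = (1/4 - x0^2)/x0^2,
// and sign(x) is conserved.  Fixed points 0, 1/2, 1 are exact.
inline double dw_relax(double rho, double t, double taurho) {
  double x = rho - 0.5;
  if (x == 0.0 || t <= 0.0) return rho;
  double q = (0.25 - x * x) / (x * x);  // > -1 always
  double e = std::exp(-t / (2.0 * taurho));
  double denom = 1.0 + q * e;
  double xnew = std::copysign(0.5 / std::sqrt(denom), x);
  return 0.5 + xnew;
}

// Durations spent above theta_p / between thresholds / below theta_d by the
// decaying exponential starting at c0 over an interval of length dt.
inline void threshold_partition(double c0, double dt, double tauCa,
                                double thd, double thp, double &tp,
                                double &tb, double &tlow) {
  double td_tot = 0.0, tp_tot = 0.0;
  if (c0 > thd) td_tot = std::min(dt, tauCa * std::log(c0 / thd));
  if (c0 > thp) tp_tot = std::min(dt, tauCa * std::log(c0 / thp));
  tp = tp_tot;
  tb = td_tot - tp_tot;
  tlow = dt - td_tot;
}

// Exact OU transition: rho' = mu + (rho-mu) e^{-t*rate} + N(0, sd(t)).
inline double ou_epoch(double rho, double t, double mu, double rate,
                       double var_stat, Rng &rng) {
  double e = std::exp(-t * rate);
  rho = mu + (rho - mu) * e;
  if (var_stat > 0.0) {
    double sd = std::sqrt(var_stat * (1.0 - e * e));
    if (sd > 0.0) rho += rng.norm() * sd;
  }
  return rho;
}

// Propagate rho across an inter-event interval of length dt during which
// calcium decays from c0 (value right after the previous jump).
inline double advance_rho(double rho, double c0, double dt,
                          const PlastParams &P, double sigma, Rng &rng) {
  if (dt <= 0.0) return rho;
  double tp, tb, tlow;
  threshold_partition(c0, dt, P.tauCa, P.thd, P.thp, tp, tb, tlow);
  if (tp > 0.0) {
    double gsum = P.gp + P.gd;
    double vs = (sigma > 0.0) ? sigma * sigma / gsum : 0.0;  // doubled noise
    rho = ou_epoch(rho, tp, P.gp / gsum, gsum / P.taurho, vs, rng);
    if (!P.double_well) rho = clip01(rho);
  }
  if (tb > 0.0) {
    double vs = (sigma > 0.0) ? sigma * sigma / (2.0 * P.gd) : 0.0;
    rho = ou_epoch(rho, tb, 0.0, P.gd / P.taurho, vs, rng);
    if (!P.double_well) rho = clip01(rho);
  }
  if (tlow > 0.0 && P.double_well) rho = dw_relax(rho, tlow, P.taurho);
  return rho;
}

// Per-synapse state for lazy event-based updates with the presynaptic
// calcium delay D.  Pending pre-calcium arrival times are kept in a small
// ring buffer (two presynaptic spikes within D is already rare at the
// firing rates of interest).
struct SynState {
  double c = 0.0;
  double rho = 0.0;
  double tlast = 0.0;
  static const int CAP = 8;
  double pend[CAP];
  int head = 0, count = 0;

  void push_pending(double t, const PlastParams &P, double sigma, Rng &rng) {
    if (count == CAP) flush_one(P, sigma, rng);
    pend[(head + count) % CAP] = t;
    ++count;
  }
  void flush_one(const PlastParams &P, double sigma, Rng &rng) {
    double te = pend[head];
    head = (head + 1) % CAP;
    --count;
    step_to(te, P.Cpre, P, sigma, rng);
  }
  // advance to time t applying pending pre-calcium arrivals first
  void advance_to(double t, const PlastParams &P, double sigma, Rng &rng) {
    while (count > 0 && pend[head] <= t) flush_one(P, sigma, rng);
    step_to(t, 0.0, P, sigma, rng);
  }
  // flush pending arrivals up to t, then apply a calcium jump amp at t
  void event_at(double t, double amp, const PlastParams &P, double sigma,
                Rng &rng) {
    while (count > 0 && pend[head] <= t) flush_one(P, sigma, rng);
    step_to(t, amp, P, sigma, rng);
  }
  // advance to time t and add an instantaneous calcium jump there
  void step_to(double t, double amp, const PlastParams &P, double sigma,
               Rng &rng) {
    double dt = t - tlast;
    if (dt > 0.0) {
      rho = advance_rho(rho, c, dt, P, sigma, rng);
      c *= std::exp(-dt / P.tauCa);
      tlast = t;
    }
    c += amp;
  }
};

}  // namespace casyn

#endif
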