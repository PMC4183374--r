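// Recurrent E/I network of leaky integrate-and-fire neurons with plastic
// E->E synapses updated event-wise by the calcium-based rule.
//
// Membrane dynamics between spike deliveries are an exact Ornstein-
// Uhlenbeck update (leak + constant external drive + white external noise):
//   V <- Veq + (V - Veq) e^{-dt/tau_m} + N(0, sd_tr),
//   sd_tr^2 = (sigma_ext^2 / 2) (1 - e^{-2 dt/tau_m}),
// with recurrent spikes delivered as voltage jumps after one step of delay.
// Subthreshold excursions between sampling points are accounted for by a
// Brownian-bridge crossing probability, which removes the O(sqrt(dt))
// threshold-crossing bias of plain Euler sampling and makes rates directly
// comparable to the Siegert formula at dt = 0.1 ms.

#include <Rcpp.h>

#include <algorithm>
#include <cmath>
#include <vector>

#include "plasticity_core.h"

using namespace Rcpp;
using casyn::PlastParams;
using casyn::Rng;
using casyn::SynState;

static PlastParams as_params2(const List &p) {
  PlastParams P;
  P.Cpre = as<double>(p["C_pre"]);
  P.Cpost = as<double>(p["C_post"]);
  P.tauCa = as<double>(p["tau_ca"]);
  P.thd = as<double>(p["theta_d"]);
  P.thp = as<double>(p["theta_p"]);
  P.gd = as<double>(p["gamma_d"]);
  P.gp = as<double>(p["gamma_p"]);
  P.sigma = as<double>(p["sigma"]);
  P.taurho = as<double>(p["tau_rho"]);
  P.rhostar = as<double>(p["rho_star"]);
  P.D = as<double>(p["D"]);
  P.double_well = as<std::string>(p["potential"]) == "double_well";
  return P;
}

// [[Rcpp::export]]
List cpp_simulate_network(List net, List params, IntegerVector edge_src,
                          IntegerVector edge_dst, IntegerVector edge_syn,
                          NumericVector rho_init, LogicalVector tagged,
                          double duration, double trace_dt, double seed,
                          bool plastic, IntegerVector fake_pre,
                          IntegerVector fake_post, NumericVector fake_rho0,
                          bool record_raster) {
  PlastParams P = as_params2(params);
  const double sigma = P.sigma;

  const int NE = as<int>(net["N_E"]);
  const int NI = as<int>(net["N_I"]);
  const int N = NE + NI;
  const double tau_m = as<double>(net["tau_m"]);
  const double VL = as<double>(net["V_L"]);
  const double Vth = as<double>(net["V_th"]);
  const double Vr = as<double>(net["V_r"]);
  const double mu_ext = as<double>(net["mu_ext"]);
  const double sig_ext = as<double>(net["sigma_ext"]);
  const double JEE = as<double>(net["J_EE_max"]);
  const double JEI = as<double>(net["J_EI"]);
  const double JIE = as<double>(net["J_IE"]);
  const double JII = as<double>(net["J_II"]);
  const double dt = as<double>(net["dt"]);

  const int nE_edges = edge_src.size();
  const long long S = rho_init.size();

  // CSR over outgoing edges
  std::vector<int> out_off(N + 1, 0), out_dst(nE_edges), out_syn(nE_edges);
  {
    std::vector<int> cnt(N, 0);
    for (int e = 0; e < nE_edges; ++e) cnt[edge_src[e]]++;
    for (int i = 0; i < N; ++i) out_off[i + 1] = out_off[i] + cnt[i];
    std::vector<int> pos(out_off.begin(), out_off.end() - 1);
    for (int e = 0; e < nE_edges; ++e) {
      int j = edge_src[e];
      out_dst[pos[j]] = edge_dst[e];
      out_syn[pos[j]] = edge_syn[e];
      ++pos[j];
    }
  }
  // incoming plastic synapses per E neuron (post-spike calcium updates)
  std::vector<int> in_off(NE + 1, 0), in_syn;
  {
    std::vector<int> cnt(NE, 0);
    for (int e = 0; e < nE_edges; ++e)
      if (edge_syn[e] >= 0) cnt[edge_dst[e]]++;
    for (int i = 0; i < NE; ++i) in_off[i + 1] = in_off[i] + cnt[i];
    in_syn.resize(in_off[NE]);
    std::vector<int> pos(in_off.begin(), in_off.end() - 1);
    for (int e = 0; e < nE_edges; ++e)
      if (edge_syn[e] >= 0) in_syn[pos[edge_dst[e]]++] = edge_syn[e];
  }

  // plastic synapse states + one RNG stream per synapse
  std::vector<SynState> syn(S);
  std::vector<Rng> syn_rng(S);
  std::vector<char> side(S);
  long long up_to_down = 0, down_to_up = 0;
  for (long long s = 0; s < S; ++s) {
    syn[s].rho = rho_init[s];
    syn_rng[s].seed((uint64_t)seed, (uint64_t)(1000000 + s));
    side[s] = rho_init[s] > P.rhostar ? 1 : 0;
  }
  auto note_side = [&](long long s) {
    char ns = syn[s].rho > P.rhostar ? 1 : 0;
    if (ns != side[s]) {
      if (side[s]) ++up_to_down; else ++down_to_up;
      side[s] = ns;
    }
  };

  // fake (non-interacting) tracked synapses
  const int NF = fake_pre.size();
  std::vector<SynState> fsyn(NF);
  std::vector<Rng> frng(NF);
  std::vector<std::vector<int>> fake_out(NE), fake_in(NE);
  for (int s = 0; s < NF; ++s) {
    fsyn[s].rho = fake_rho0[s];
    frng[s].seed((uint64_t)seed, (uint64_t)(5000000 + s));
    fake_out[fake_pre[s]].push_back(s);
    fake_in[fake_post[s]].push_back(s);
  }

  // membrane state
  std::vector<double> V(N);
  std::vector<Rng> vrng(N);
  for (int i = 0; i < N; ++i) {
    vrng[i].seed((uint64_t)seed, (uint64_t)(9000000 + i));
    V[i] = Vr + (Vth - Vr) * vrng[i].unif();
  }
  std::vector<double> cur_jump(N, 0.0), next_jump(N, 0.0);

  const double decay = std::exp(-dt / tau_m);
  const double Veq = VL + mu_ext;
  const double tr_sd =
      std::sqrt(0.5 * sig_ext * sig_ext * (1.0 - decay * decay));
  const double bridge_var = sig_ext * sig_ext * dt / tau_m;
  const double bridge_win = 5.0 * std::sqrt(bridge_var);

  const long long nsteps = (long long)std::llround(duration / dt);
  const int nbins = std::max(1, (int)std::floor(duration / trace_dt + 1e-9));
  std::vector<int> cntE(nbins, 0), cntI(nbins, 0);
  int ntr = (int)std::floor(duration / trace_dt + 1e-9) + 1;
  std::vector<double> tr_time(ntr), tr_tag(ntr, 0.0), tr_untag(ntr, 0.0),
      tr_fake(ntr, 0.0);
  long long n_tag = 0, n_untag = 0;
  for (long long s = 0; s < S; ++s) (tagged[s] ? n_tag : n_untag)++;

  std::vector<double> sp_t;
  std::vector<int> sp_id;

  auto sample_traces = [&](int k, double tnow) {
    double st = 0.0, su = 0.0, sf = 0.0;
    for (long long s = 0; s < S; ++s) {
      if (plastic) {
        syn[s].advance_to(tnow, P, sigma, syn_rng[s]);
        note_side(s);
      }
      if (tagged[s]) st += syn[s].rho; else su += syn[s].rho;
    }
    for (int s = 0; s < NF; ++s) {
      fsyn[s].advance_to(tnow, P, sigma, frng[s]);
      sf += fsyn[s].rho;
    }
    tr_time[k] = tnow;
    tr_tag[k] = n_tag ? st / n_tag : NA_REAL;
    tr_untag[k] = n_untag ? su / n_untag : NA_REAL;
    tr_fake[k] = NF ? sf / NF : NA_REAL;
  };
  sample_traces(0, 0.0);
  int next_tr = 1;

  for (long long step = 0; step < nsteps; ++step) {
    double tnow = (step + 1) * dt;
    std::swap(cur_jump, next_jump);
    std::fill(next_jump.begin(), next_jump.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      double Vold = V[i];
      double v = Veq + (Vold - Veq) * decay + tr_sd * vrng[i].norm() +
                 cur_jump[i];
      bool spike = v >= Vth;
      if (!spike && Vold < Vth && Vth - std::max(Vold, v) < bridge_win) {
        double pb = std::exp(-2.0 * (Vth - Vold) * (Vth - v) / bridge_var);
        if (vrng[i].unif() < pb) spike = true;
      }
      if (spike) {
        V[i] = Vr;
        if (record_raster) {
          sp_t.push_back(tnow);
          sp_id.push_back(i);
        }
        int b = std::min(nbins - 1, (int)(tnow / trace_dt));
        (i < NE ? cntE : cntI)[b]++;
        // recurrent delivery (one-step delay)
        for (int e = out_off[i]; e < out_off[i + 1]; ++e) {
          int d = out_dst[e];
          int sid = out_syn[e];
          double w;
          if (sid >= 0) {
            if (plastic) {
              syn[sid].advance_to(tnow, P, sigma, syn_rng[sid]);
              note_side(sid);
              w = JEE * syn[sid].rho;
              syn[sid].push_pending(tnow + P.D, P, sigma, syn_rng[sid]);
            } else {
              w = JEE * rho_init[sid];
            }
          } else {
            if (i < NE) {
              w = JIE;  // E source onto I target
            } else {
              w = (d < NE) ? JEI : JII;
            }
          }
          next_jump[d] += w;
        }
        // plasticity bookkeeping for E spikes
        if (i < NE) {
          if (plastic) {
            for (int e = in_off[i]; e < in_off[i + 1]; ++e) {
              int sid = in_syn[e];
              syn[sid].event_at(tnow, P.Cpost, P, sigma, syn_rng[sid]);
              note_side(sid);
            }
          }
          for (int s : fake_out[i]) {
            fsyn[s].advance_to(tnow, P, sigma, frng[s]);
            fsyn[s].push_pending(tnow + P.D, P, sigma, frng[s]);
          }
          for (int s : fake_in[i]) {
            fsyn[s].event_at(tnow, P.Cpost, P, sigma, frng[s]);
          }
        }
      } else {
        V[i] = v;
      }
    }
    if (next_tr < ntr && tnow + 1e-9 >= next_tr * trace_dt) {
      sample_traces(next_tr, next_tr * trace_dt);
      ++next_tr;
    }
  }

  NumericVector rateE(nbins), rateI(nbins), bin_t(nbins);
  for (int b = 0; b < nbins; ++b) {
    bin_t[b] = (b + 0.5) * trace_dt;
    rateE[b] = cntE[b] / (trace_dt * NE);
    rateI[b] = cntI[b] / (trace_dt * NI);
  }
  NumericVector rho_final(S), fake_final(NF);
  for (long long s = 0; s < S; ++s) rho_final[s] = syn[s].rho;
  for (int s = 0; s < NF; ++s) fake_final[s] = fsyn[s].rho;

  return List::create(
      _["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["bin_time"] = bin_t, _["rate_E"] = rateE, _["rate_I"] = rateI,
      _["trace_time"] = NumericVector(tr_time.begin(), tr_time.end()),
      _["rho_tagged"] = NumericVector(tr_tag.begin(), tr_tag.end()),
      _["rho_untagged"] = NumericVector(tr_untag.begin(), tr_untag.end()),
      _["rho_fake"] = NumericVector(tr_fake.begin(), tr_fake.end()),
      _["rho_final"] = rho_final, _["fake_rho_final"] = fake_final,
      _["up_to_down"] = (double)up_to_down,
      _["down_to_up"] = (double)down_to_up);
}

// Independent LIF neurons with white-noise drive only (no recurrence);
// returns the spike raster.  Same exact-update + bridge machinery.
// [[Rcpp::export]]
List cpp_simulate_lif(int n, double duration, double tau_m, double VL,
                      double Vth, double Vr, double mu_ext, double sig_ext,
                      double dt, double seed) {
  std::vector<double> sp_t;
  std::vector<int> sp_id;
  const double decay = std::exp(-dt / tau_m);
  const double Veq = VL + mu_ext;
  const double tr_sd =
      std::sqrt(0.5 * sig_ext * sig_ext * (1.0 - decay * decay));
  const double bridge_var = sig_ext * sig_ext * dt / tau_m;
  const double bridge_win = 5.0 * std::sqrt(bridge_var);
  const long long nsteps = (long long)std::llround(duration / dt);
  for (int i = 0; i < n; ++i) {
    Rng rng((uint64_t)seed, (uint64_t)(42 + i));
    double V = Vr + (Vth - Vr) * rng.unif();
    for (long long step = 0; step < nsteps; ++step) {
      double Vold = V;
      double v = Veq + (Vold - Veq) * decay + tr_sd * rng.norm();
      bool spike = v >= Vth;
      if (!spike && Vth - std::max(Vold, v) < bridge_win) {
        double pb = std::exp(-2.0 * (Vth - Vold) * (Vth - v) / bridge_var);
        if (rng.unif() < pb) spike = true;
      }
      if (spike) {
        V = Vr;
        sp_t.push_back((step + 1) * dt);
        sp_id.push_back(i);
      } else {
        V = v;
      }
    }
  }
  return List::create(_["spike_time"] = NumericVector(sp_t.begin(), sp_t.end()),
                      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()));
}
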