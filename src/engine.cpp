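// Event-based synapse engine: single traces, Euler reference integrator,
// ensembles driven by independent Poisson pairs, first-passage runs, and a
// Monte-Carlo estimator of the calcium threshold fractions.

#include <Rcpp.h>

#include <algorithm>
#include <vector>

#include "plasticity_core.h"

using namespace Rcpp;
using casyn::PlastParams;
using casyn::Rng;
using casyn::SynState;

static PlastParams as_params(const List &p) {
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

struct Event {
  double t;
  double amp;
  bool sample;  // zero-amplitude sampling event
};

// merged, time-sorted event list: pre spikes shifted by D, post spikes as
// is, optional sampling grid; coincident calcium jumps are coalesced into a
// single jump so that RNG consumption is order-independent
static std::vector<Event> build_events(const NumericVector &pre,
                                       const NumericVector &post,
                                       const PlastParams &P, double t_end,
                                       double sample_dt) {
  std::vector<Event> ev;
  ev.reserve(pre.size() + post.size() + 16);
  for (double t : pre) ev.push_back({t + P.D, P.Cpre, false});
  for (double t : post) ev.push_back({t, P.Cpost, false});
  if (sample_dt > 0) {
    for (double t = sample_dt; t <= t_end + 1e-12; t += sample_dt)
      ev.push_back({t, 0.0, true});
  }
  ev.push_back({t_end, 0.0, true});
  std::stable_sort(ev.begin(), ev.end(),
                   [](const Event &a, const Event &b) { return a.t < b.t; });
  // coalesce strictly coincident jumps
  std::vector<Event> out;
  for (const Event &e : ev) {
    if (!out.empty() && !e.sample && !out.back().sample &&
        std::fabs(e.t - out.back().t) < 1e-12) {
      out.back().amp += e.amp;
    } else {
      out.push_back(e);
    }
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_run_synapse(NumericVector pre, NumericVector post, List params,
                          double rho0, double c0, double seed, double stream,
                          double t_end, double sample_dt,
                          double sigma_scale) {
  PlastParams P = as_params(params);
  double sigma = P.sigma * sigma_scale;
  Rng rng((uint64_t)seed, (uint64_t)stream);
  std::vector<Event> ev = build_events(pre, post, P, t_end, sample_dt);

  std::vector<double> ts, cs, rhos;
  ts.reserve(ev.size() + 1);
  cs.reserve(ev.size() + 1);
  rhos.reserve(ev.size() + 1);

  double c = c0, rho = rho0, tlast = 0.0;
  ts.push_back(0.0);
  cs.push_back(c);
  rhos.push_back(rho);
  for (const Event &e : ev) {
    if (e.t > t_end + 1e-12) break;
    double dt = e.t - tlast;
    if (dt < 0) stop("events are not sorted");
    rho = casyn::advance_rho(rho, c, dt, P, sigma, rng);
    c = c * std::exp(-dt / P.tauCa) + e.amp;
    tlast = e.t;
    ts.push_back(e.t);
    cs.push_back(c);
    rhos.push_back(rho);
  }
  return DataFrame::create(_["time"] = ts, _["calcium"] = cs,
                           _["rho"] = rhos);
}

// Reference integrator: forward Euler at a small fixed step on the full
// stochastic differential equation (quartic potential included in every
// region).  Used as an independent oracle for the event-based scheme.
// [[Rcpp::export]]
DataFrame cpp_run_euler(NumericVector pre, NumericVector post, List params,
                        double rho0, double c0, double dt_step, double seed,
                        double stream, double t_end, double sample_dt,
                        double sigma_scale) {
  PlastParams P = as_params(params);
  double sigma = P.sigma * sigma_scale;
  Rng rng((uint64_t)seed, (uint64_t)stream);

  // merged jump times (pre shifted by D), coalesced
  std::vector<Event> ev = build_events(pre, post, P, t_end, 0.0);

  std::vector<double> ts, cs, rhos;
  double c = c0, rho = rho0, t = 0.0;
  size_t ie = 0;
  double next_sample = 0.0;
  double decay = std::exp(-dt_step / P.tauCa);
  double sqdt = std::sqrt(dt_step / P.taurho);
  while (t < t_end - 1e-12) {
    if (sample_dt > 0 && t >= next_sample - 1e-12) {
      ts.push_back(t);
      cs.push_back(c);
      rhos.push_back(rho);
      next_sample += sample_dt;
    }
    // apply jumps due in (t, t+dt]
    double hp = (c > P.thp) ? 1.0 : 0.0;
    double hd = (c > P.thd) ? 1.0 : 0.0;
    double bare = 0.0;
    if (P.double_well) bare = -rho * (1.0 - rho) * (P.rhostar - rho);
    double drift =
        bare + P.gp * (1.0 - rho) * hp - P.gd * rho * hd;
    double dn = 0.0;
    if (sigma > 0 && hd > 0) dn = sigma * std::sqrt(hd + hp) * sqdt * rng.norm();
    rho += drift * dt_step / P.taurho + dn;
    if (!P.double_well) rho = casyn::clip01(rho);
    c *= decay;
    t += dt_step;
    while (ie < ev.size() && !ev[ie].sample && ev[ie].t <= t + 1e-12) {
      c += ev[ie].amp;
      ++ie;
    }
  }
  ts.push_back(t);
  cs.push_back(c);
  rhos.push_back(rho);
  return DataFrame::create(_["time"] = ts, _["calcium"] = cs,
                           _["rho"] = rhos);
}

// generate a sorted homogeneous Poisson train on [0, duration)
static std::vector<double> poisson_train(double rate, double duration,
                                         Rng &rng) {
  std::vector<double> t;
  if (rate <= 0) return t;
  double s = rng.expo(rate);
  while (s < duration) {
    t.push_back(s);
    s += rng.expo(rate);
  }
  return t;
}

// Ensemble of independent synapses, each driven by its own pre/post Poisson
// pair; per-synapse streams are keyed by (seed, id) so results do not
// depend on execution order.  Returns the time-binned ensemble mean and the
// final efficacies.
// [[Rcpp::export]]
List cpp_run_ensemble(int n, double nu_pre, double nu_post, double duration,
                      List params, double rho0, double seed, double bin_dt,
                      double sigma_scale) {
  PlastParams P = as_params(params);
  double sigma = P.sigma * sigma_scale;
  int nb = (int)std::floor(duration / bin_dt + 1e-9) + 1;
  std::vector<double> sum(nb, 0.0), sumsq(nb, 0.0);
  NumericVector final_rho(n);

  for (int k = 0; k < n; ++k) {
    Rng rng((uint64_t)seed, (uint64_t)(2 * k));
    Rng rng_noise((uint64_t)seed, (uint64_t)(2 * k + 1));
    std::vector<double> pre = poisson_train(nu_pre, duration, rng);
    std::vector<double> post = poisson_train(nu_post, duration, rng);
    // merged events incl. sampling grid
    size_t ip = 0, iq = 0;
    double c = 0.0, rho = rho0, tlast = 0.0;
    int ib = 0;
    auto record = [&](double tnow) {
      while (ib < nb && ib * bin_dt <= tnow + 1e-12) {
        double tb = ib * bin_dt;
        double dtb = tb - tlast;
        double rv = rho, cv = c * std::exp(-dtb / P.tauCa);
        // sample exactly at bin edge by advancing a copy
        Rng tmp = rng_noise;  // copy: sampling must not perturb the path
        rv = casyn::advance_rho(rho, c, dtb, P, sigma, tmp);
        (void)cv;
        sum[ib] += rv;
        sumsq[ib] += rv * rv;
        ++ib;
      }
    };
    record(0.0);
    while (ip < pre.size() || iq < post.size()) {
      double tp = ip < pre.size() ? pre[ip] + P.D : 1e300;
      double tq = iq < post.size() ? post[iq] : 1e300;
      double te;
      double amp;
      if (std::fabs(tp - tq) < 1e-12 && tp < 1e299) {
        te = tp;
        amp = P.Cpre + P.Cpost;
        ++ip;
        ++iq;
      } else if (tp < tq) {
        te = tp;
        amp = P.Cpre;
        ++ip;
      } else {
        te = tq;
        amp = P.Cpost;
        ++iq;
      }
      if (te >= duration) break;
      record(te);
      double dt = te - tlast;
      rho = casyn::advance_rho(rho, c, dt, P, sigma, rng_noise);
      c = c * std::exp(-dt / P.tauCa) + amp;
      tlast = te;
    }
    record(duration);
    final_rho[k] = rho;
  }
  NumericVector tb(nb), mean(nb), sd(nb);
  for (int i = 0; i < nb; ++i) {
    tb[i] = i * bin_dt;
    mean[i] = sum[i] / n;
    double v = sumsq[i] / n - mean[i] * mean[i];
    sd[i] = v > 0 ? std::sqrt(v) : 0.0;
  }
  return List::create(_["time"] = tb, _["mean_rho"] = mean,
                      _["sd_rho"] = sd, _["final_rho"] = final_rho);
}

// First-passage runs: start at rho0, simulate until rho first crosses
// rho_stop downward (checked after every event update) or t_max.
// [[Rcpp::export]]
List cpp_first_passage(int n, double nu_pre, double nu_post, List params,
                       double rho0, double rho_stop, double t_max,
                       double seed, double sigma_scale) {
  PlastParams P = as_params(params);
  double sigma = P.sigma * sigma_scale;
  NumericVector times(n);
  LogicalVector censored(n);
  for (int k = 0; k < n; ++k) {
    Rng rng((uint64_t)seed, (uint64_t)k);
    double c = 0.0, rho = rho0, t = 0.0;
    double nutot = nu_pre + nu_post;
    bool crossed = false;
    if (nutot > 0) {
      while (t < t_max) {
        double dt = rng.expo(nutot);
        double te = t + dt;
        if (te > t_max) te = t_max;
        rho = casyn::advance_rho(rho, c, te - t, P, sigma, rng);
        c = c * std::exp(-(te - t) / P.tauCa);
        if (te < t_max) {
          c += (rng.unif() * nutot < nu_pre) ? P.Cpre : P.Cpost;
        }
        t = te;
        if (rho < rho_stop) {
          crossed = true;
          break;
        }
      }
    } else {
      t = t_max;
    }
    times[k] = t;
    censored[k] = !crossed;
  }
  return List::create(_["time"] = times, _["censored"] = censored);
}

// Monte-Carlo oracle for the stationary threshold fractions: simulate the
// calcium shot noise alone event-by-event and accumulate the exact time
// above each threshold; block means give standard errors.
// [[Rcpp::export]]
List cpp_mc_alpha(double nu_pre, double nu_post, double Cpre, double Cpost,
                  double tauCa, double thd, double thp, double n_events,
                  double seed, int n_blocks) {
  Rng rng((uint64_t)seed, 1234567ULL);
  double nutot = nu_pre + nu_post;
  if (nutot <= 0) {
    return List::create(_["alpha_d"] = 0.0, _["alpha_p"] = 0.0,
                        _["se_d"] = 0.0, _["se_p"] = 0.0);
  }
  long long N = (long long)n_events;
  long long per_block = N / n_blocks;
  std::vector<double> bd, bp;
  double c = 0.0;
  for (int b = 0; b < n_blocks; ++b) {
    double above_d = 0.0, above_p = 0.0, T = 0.0;
    for (long long i = 0; i < per_block; ++i) {
      double dt = rng.expo(nutot);
      if (c > thd) above_d += std::min(dt, tauCa * std::log(c / thd));
      if (c > thp) above_p += std::min(dt, tauCa * std::log(c / thp));
      c = c * std::exp(-dt / tauCa) +
          ((rng.unif() * nutot < nu_pre) ? Cpre : Cpost);
      T += dt;
    }
    bd.push_back(above_d / T);
    bp.push_back(above_p / T);
  }
  double md = 0, mp = 0;
  for (int b = 0; b < n_blocks; ++b) {
    md += bd[b];
    mp += bp[b];
  }
  md /= n_blocks;
  mp /= n_blocks;
  double vd = 0, vp = 0;
  for (int b = 0; b < n_blocks; ++b) {
    vd += (bd[b] - md) * (bd[b] - md);
    vp += (bp[b] - mp) * (bp[b] - mp);
  }
  double sed = std::sqrt(vd / (n_blocks - 1) / n_blocks);
  double sep = std::sqrt(vp / (n_blocks - 1) / n_blocks);
  return List::create(_["alpha_d"] = md, _["alpha_p"] = mp, _["se_d"] = sed,
                      _["se_p"] = sep);
}

// Exposed epoch primitives (thin wrappers used by the R-level operations)

// [[Rcpp::export]]
NumericVector cpp_ou_epoch_sample(int n, double rho, double t, double target,
                                  double rate, double var_stat, double seed) {
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    Rng rng((uint64_t)seed, (uint64_t)k);
    out[k] = casyn::ou_epoch(rho, t, target, rate, var_stat, rng);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_dw_relax(double rho, double t, double taurho) {
  return casyn::dw_relax(rho, t, taurho);
}
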