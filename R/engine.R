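#' Event-based propagation of a single synapse
#'
#' Runs the exact event-based update scheme of the calcium-based plasticity
#' model on given pre- and postsynaptic spike trains.  Presynaptic calcium
#' transients are applied with delay `D` after the presynaptic spike;
#' coincident calcium jumps are merged into a single jump so that the
#' update (and the noise-stream consumption) is independent of tie-breaking
#' order.  Between events the efficacy is propagated in a piecewise manner:
#' exact Ornstein-Uhlenbeck updates over the epochs the calcium trace
#' spends above the potentiation threshold (doubled noise variance) and
#' between the thresholds (single noise), then the deterministic
#' subthreshold update (identity for the flat potential, the integrated
#' double-well flow otherwise).  In flat-potential mode the efficacy is
#' clipped to `[0, 1]` after each stochastic epoch, realising the
#' truncation of the OU process.
#'
#' @param pre,post sorted vectors of spike times (s).
#' @param p a [plasticity_params()] object.
#' @param rho0 initial efficacy.
#' @param duration end of the simulated interval (s); defaults to the last
#'   event time.
#' @param seed RNG seed; identical seeds give identical traces.
#' @param stream substream id (used to decorrelate synapses in ensembles).
#' @param sample_dt optional regular sampling interval (s); sampling events
#'   carry zero calcium and leave the trajectory distribution unchanged.
#' @param sigma_scale multiplier on the noise amplitude (e.g. 0 for the
#'   deterministic system).
#' @param c0 initial calcium.
#' @return A data frame with columns `time`, `calcium`, `rho` recorded at
#'   every event (calcium is the value right after the jump).
#' @examples
#' p <- ca_preset("in_vivo")
#' tr <- run_synapse(pre = c(0.1, 0.5), post = c(0.3), p, rho0 = 0.5,
#'                   duration = 1, sigma_scale = 0)
#' @export
run_synapse <- function(pre, post, p, rho0 = 1, duration = NULL, seed = 1,
                        stream = 0, sample_dt = 0, sigma_scale = 1,
                        c0 = 0) {
  stopifnot(inherits(p, "plasticity_params"))
  if (is.unsorted(pre) || is.unsorted(post))
    stop("spike trains must be sorted in time")
  if (is.null(duration))
    duration <- max(c(pre + p$D, post, 0))
  cpp_run_synapse(as.numeric(pre), as.numeric(post), unclass(p), rho0, c0,
                  seed, stream, duration, sample_dt, sigma_scale)
}

#' Fixed-step Euler reference integration of a synapse
#'
#' Independent reference integrator for [run_synapse()]: forward Euler at a
#' small fixed step on the full stochastic differential equation, with the
#' quartic potential retained in every calcium region.  With
#' `sigma_scale = 0` both integrators are deterministic and can be compared
#' pathwise.
#'
#' @inheritParams run_synapse
#' @param dt_step Euler step (s); the reference resolution is 1e-6 s
#'   (0.001 ms).
#' @return A data frame with columns `time`, `calcium`, `rho` sampled every
#'   `sample_dt` (plus the final time).
#' @export
run_synapse_euler <- function(pre, post, p, rho0 = 1, duration = NULL,
                              dt_step = 1e-6, seed = 1, stream = 0,
                              sample_dt = 0.01, sigma_scale = 1, c0 = 0) {
  stopifnot(inherits(p, "plasticity_params"))
  if (is.unsorted(pre) || is.unsorted(post))
    stop("spike trains must be sorted in time")
  if (is.null(duration))
    duration <- max(c(pre + p$D, post, 0))
  cpp_run_euler(as.numeric(pre), as.numeric(post), unclass(p), rho0, c0,
                dt_step, seed, stream, duration, sample_dt, sigma_scale)
}

#' Advance a synapse state across one inter-event interval
#'
#' Single-step version of the event-based update: partitions the interval
#' with [threshold_partition()], applies the suprathreshold stochastic
#' epochs and the deterministic subthreshold update in temporal order, and
#' finally decays the calcium.
#'
#' @param state list with fields `calcium` (value after the last jump),
#'   `rho`, and `t_last` (s).
#' @param dt nonnegative interval length (s).
#' @param p a [plasticity_params()] object.
#' @param seed,stream RNG keys for the stochastic epochs.
#' @param sigma_scale noise multiplier.
#' @return Updated state list.
#' @export
advance_synapse <- function(state, dt, p, seed = 1, stream = 0,
                            sigma_scale = 1) {
  stopifnot(inherits(p, "plasticity_params"))
  if (dt < 0) stop("dt must be nonnegative")
  tr <- cpp_run_synapse(numeric(0), numeric(0), unclass(p), state$rho,
                        state$calcium, seed, stream, dt, 0, sigma_scale)
  n <- nrow(tr)
  list(calcium = tr$calcium[n], rho = tr$rho[n], t_last = state$t_last + dt)
}

#' Exact Ornstein-Uhlenbeck epoch update
#'
#' Transition of a suprathreshold epoch: relaxation toward `target` at
#' `rate` plus a Gaussian increment with the exact OU transition standard
#' deviation `sd(t) = sqrt(var_stat (1 - exp(-2 t rate)))`.
#'
#' @param rho efficacy at epoch start.
#' @param t epoch duration (s), nonnegative.
#' @param target drift target.
#' @param rate relaxation rate (1/s).
#' @param var_stat stationary variance of the epoch's OU process.
#' @param n number of independent samples to draw.
#' @param seed RNG seed.
#' @return Numeric vector of `n` updated efficacies.
#' @export
stochastic_epoch_update <- function(rho, t, target, rate, var_stat,
                                    n = 1L, seed = 1) {
  if (t < 0) stop("epoch length must be nonnegative")
  cpp_ou_epoch_sample(as.integer(n), rho, t, target, rate, var_stat, seed)
}

#' Deterministic subthreshold updates
#'
#' Below the depression threshold the efficacy follows the bare potential
#' only.  For the flat potential this is the identity; for the symmetric
#' double well (`rho_star = 1/2`) the flow `tau drho/dt = -U'(rho)` with
#' `U(rho) = rho^2 (1-rho)^2 / 4` integrates in closed form: with
#' `x = rho - 1/2`, `x(t)^2 = (1/4) / (1 + q e^{-t/(2 tau)})`,
#' `q = (1/4 - x0^2)/x0^2`, with the sign of `x` conserved.  The fixed
#' points 0, 1/2, 1 are exact.
#'
#' @param rho efficacy.
#' @param t elapsed time (s), nonnegative.
#' @param tau_rho efficacy time constant (s).
#' @param rho_star barrier position (must be 1/2).
#' @return Updated efficacy.
#' @export
deterministic_update_flat <- function(rho, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  rho
}

#' @rdname deterministic_update_flat
#' @export
deterministic_update_double_well <- function(rho, t, tau_rho,
                                             rho_star = 0.5) {
  if (any(t < 0)) stop("t must be nonnegative")
  if (abs(rho_star - 0.5) > 1e-12)
    stop("closed-form double-well update requires rho_star = 0.5")
  vapply(seq_along(rho), function(i) {
    cpp_dw_relax(rho[i], if (length(t) > 1) t[i] else t, tau_rho)
  }, numeric(1))
}

#' Ensemble of independent Poisson-driven synapses
#'
#' Simulates `n_synapses` statistically independent synapses, each driven
#' by its own pre/post pair of independent Poisson spike trains, using the
#' event-based engine.  Per-synapse RNG streams are keyed by
#' `(seed, synapse id)`, so results are reproducible and independent of
#' execution order.
#'
#' @param config an [experiment_config()] object.
#' @param p a [plasticity_params()] object.
#' @param bin_dt time bin for the ensemble-mean trace (s).
#' @param sigma_scale noise multiplier.
#' @return List with `trace` (data frame: `time`, `mean_rho`, `sd_rho`) and
#'   `final_rho` (vector of final efficacies).
#' @examples
#' cfg <- experiment_config(1, 1, duration = 60, n_synapses = 10, seed = 7)
#' out <- run_ensemble(cfg, ca_preset("in_vitro"))
#' @export
run_ensemble <- function(config, p, bin_dt = NULL, sigma_scale = 1) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(p, "plasticity_params"))
  if (is.null(bin_dt)) bin_dt <- max(config$duration / 200, 0.5)
  res <- cpp_run_ensemble(config$n_synapses, config$nu_pre, config$nu_post,
                          config$duration, unclass(p), config$rho_init,
                          config$seed, bin_dt, sigma_scale)
  list(trace = data.frame(time = res$time, mean_rho = res$mean_rho,
                          sd_rho = res$sd_rho),
       final_rho = res$final_rho)
}

#' First-passage times out of the UP state
#'
#' Simulates synapses initialised at `rho0` under symmetric Poisson firing
#' until the efficacy first crosses `rho_stop` downward, or until `t_max`
#' (censored).
#'
#' @param n number of independent runs.
#' @param nu pre- and postsynaptic rate (spikes/s each).
#' @param p a [plasticity_params()] object.
#' @param rho0 initial efficacy.
#' @param rho_stop crossing level (defaults to the barrier position).
#' @param t_max censoring horizon (s).
#' @param seed RNG seed.
#' @param sigma_scale noise multiplier (elevated noise makes direct escape
#'   simulations feasible).
#' @return Data frame with columns `time` and `censored`.
#' @export
simulate_first_passage <- function(n, nu, p, rho0 = 1, rho_stop = NULL,
                                   t_max = Inf, seed = 1, sigma_scale = 1) {
  stopifnot(inherits(p, "plasticity_params"))
  if (is.null(rho_stop)) rho_stop <- p$rho_star
  res <- cpp_first_passage(as.integer(n), nu, nu, unclass(p), rho0,
                           rho_stop, t_max, seed, sigma_scale)
  data.frame(time = res$time, censored = res$censored)
}
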