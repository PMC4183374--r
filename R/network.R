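#' Parameters of the recurrent LIF network
#'
#' Scaled-down excitatory/inhibitory network of leaky integrate-and-fire
#' neurons with plastic E-to-E synapses.  The default configuration
#' (800 E + 200 I, connection probability 0.1) is designed with the
#' mean-field solver to sit in an inhibition-dominated asynchronous
#' irregular state with excitatory rates near 1/s; all values are exposed
#' and can be overridden.  The transmission delay equals the integration
#' step.  The refractory period is zero.
#'
#' @param N_E,N_I population sizes.
#' @param p_conn uniform connection probability (autapses excluded).
#' @param tau_m membrane time constant (s).
#' @param V_L,V_th,V_r leak, threshold and reset potentials (mV).
#' @param mu_ext constant external drive (mV above leak).
#' @param sigma_ext white-noise amplitude of the external drive (mV),
#'   uncorrelated across neurons.
#' @param J_EE_max maximal E-to-E jump (mV); the delivered jump is
#'   `J_EE_max * rho`.
#' @param J_EI,J_IE,J_II fixed jumps (mV): I-to-E, E-to-I, I-to-I
#'   (inhibitory values negative).
#' @param dt integration step (s); also the transmission delay.
#' @return Object of class `network_params`.
#' @export
network_params <- function(N_E = 800L, N_I = 200L, p_conn = 0.1,
                           tau_m = 20e-3, V_L = -70, V_th = -50, V_r = -60,
                           mu_ext = 10.6, sigma_ext = 5,
                           J_EE_max = 0.6, J_EI = -1.6, J_IE = 0.3,
                           J_II = -1.6, dt = 1e-4) {
  if (V_r >= V_th) stop("reset must be below threshold")
  if (p_conn <= 0 || p_conn > 1) stop("p_conn must be in (0, 1]")
  if (N_E < 1 || N_I < 1) stop("both populations need at least one neuron")
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 p_conn = p_conn, tau_m = tau_m, V_L = V_L, V_th = V_th,
                 V_r = V_r, refractory = 0, mu_ext = mu_ext,
                 sigma_ext = sigma_ext, J_EE_max = J_EE_max, J_EI = J_EI,
                 J_IE = J_IE, J_II = J_II, delay = dt, dt = dt),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("LIF network: %d E + %d I, p = %g, tau_m = %g ms\n",
              x$N_E, x$N_I, x$p_conn, 1e3 * x$tau_m))
  cat(sprintf("  V_L/V_th/V_r = %g/%g/%g mV, mu_ext = %g mV, sigma_ext = %g mV\n",
              x$V_L, x$V_th, x$V_r, x$mu_ext, x$sigma_ext))
  cat(sprintf("  J: EE_max %g, EI %g, IE %g, II %g mV; dt = delay = %g ms\n",
              x$J_EE_max, x$J_EI, x$J_IE, x$J_II, 1e3 * x$dt))
  invisible(x)
}

#' Build the random connectivity of the network
#'
#' Bernoulli(`p_conn`) adjacency, uniform across population pairs, with
#' autapses explicitly disallowed.  E-to-E edges receive consecutive
#' plastic-synapse ids.
#'
#' @param net a [network_params()] object.
#' @param seed RNG seed (uses and restores R's RNG state).
#' @return List with 0-based `src`, `dst`, `syn` (plastic id or -1) and
#'   `n_syn`, the number of plastic E-to-E synapses.
#' @export
build_adjacency <- function(net, seed = 1) {
  stopifnot(inherits(net, "network_params"))
  N <- net$N_E + net$N_I
  edges <- with_local_seed(seed, {
    src <- integer(0); dst <- integer(0)
    for (j in seq_len(N) - 1L) {
      tgt <- which(stats::runif(N) < net$p_conn) - 1L
      tgt <- tgt[tgt != j]
      src <- c(src, rep.int(j, length(tgt)))
      dst <- c(dst, tgt)
    }
    list(src = src, dst = dst)
  })
  is_ee <- edges$src < net$N_E & edges$dst < net$N_E
  syn <- rep.int(-1L, length(edges$src))
  syn[is_ee] <- seq_len(sum(is_ee)) - 1L
  list(src = edges$src, dst = edges$dst, syn = syn, n_syn = sum(is_ee))
}

#' Simulate the recurrent network
#'
#' Runs the scaled network with event-wise plastic E-to-E synapses.
#' Membrane potentials follow an exact Ornstein-Uhlenbeck update between
#' spike deliveries with a Brownian-bridge threshold-crossing correction;
#' spikes are delivered with a one-step delay; presynaptic calcium
#' transients arrive with delay `D` inside the synapse model.
#'
#' @param net a [network_params()] object.
#' @param p a [plasticity_params()] object.
#' @param duration simulated time (s).
#' @param seed seed for connectivity, initial conditions and all noise.
#' @param rho_init either a numeric vector (one value per plastic synapse,
#'   recycled), `"stationary_cdf"` (reverse-lookup sampling from the
#'   stationary efficacy distribution at `stationary_rate`), or a single
#'   constant.
#' @param stationary_rate rate (spikes/s) at which the stationary
#'   efficacy distribution is evaluated for `rho_init = "stationary_cdf"`.
#' @param tag_fraction fraction of plastic synapses set to `rho = 1` at
#'   the start (the implanted memory); 0 disables tagging.
#' @param plastic if `FALSE`, synaptic weights stay frozen at their
#'   initial values (plasticity off).
#' @param n_fake number of non-interacting tracked synapses assigned to
#'   random E neuron pairs; they obey the plasticity rule driven by the
#'   network spikes but do not influence the dynamics.
#' @param trace_dt sampling interval for rate and efficacy traces (s).
#' @param record_raster keep the full spike raster.
#' @return Object of class `network_result`: rate traces, tagged/untagged/
#'   fake mean-efficacy traces, final efficacies, well-transition counts,
#'   the raster (if recorded), and the realised adjacency summary.
#' @export
simulate_network <- function(net, p, duration, seed = 1,
                             rho_init = "stationary_cdf",
                             stationary_rate = 1,
                             tag_fraction = 0, plastic = TRUE,
                             n_fake = 0L, trace_dt = 1,
                             record_raster = TRUE) {
  stopifnot(inherits(net, "network_params"),
            inherits(p, "plasticity_params"))
  adj <- build_adjacency(net, seed = seed)
  S <- adj$n_syn
  if (is.character(rho_init) && rho_init == "stationary_cdf") {
    rho0 <- sample_stationary_rho(S, stationary_rate, p, seed = seed + 1)
  } else {
    rho0 <- rep_len(as.numeric(rho_init), S)
  }
  tagged <- rep(FALSE, S)
  if (tag_fraction > 0) {
    idx <- with_local_seed(seed + 2,
                           sample.int(S, round(tag_fraction * S)))
    tagged[idx] <- TRUE
    rho0[tagged] <- 1
  }
  fake_pre <- fake_post <- integer(0)
  fake_rho0 <- numeric(0)
  if (n_fake > 0) {
    pairs <- with_local_seed(seed + 3, {
      pre <- sample.int(net$N_E, n_fake, replace = TRUE) - 1L
      post <- sample.int(net$N_E, n_fake, replace = TRUE) - 1L
      shift <- post == pre
      post[shift] <- (post[shift] + 1L) %% net$N_E
      list(pre = pre, post = post)
    })
    fake_pre <- pairs$pre
    fake_post <- pairs$post
    fake_rho0 <- rep_len(if (S > 0) rho0[!tagged][1] else 0.2, n_fake)
  }
  res <- cpp_simulate_network(unclass(net), unclass(p),
                              as.integer(adj$src), as.integer(adj$dst),
                              as.integer(adj$syn), rho0, tagged, duration,
                              trace_dt, seed, plastic,
                              as.integer(fake_pre), as.integer(fake_post),
                              fake_rho0, record_raster)
  structure(list(
    rates = data.frame(time = res$bin_time, rate_E = res$rate_E,
                       rate_I = res$rate_I),
    rho_traces = data.frame(time = res$trace_time,
                            tagged = res$rho_tagged,
                            untagged = res$rho_untagged,
                            fake = res$rho_fake),
    raster = if (record_raster)
      data.frame(time = res$spike_time, neuron = res$spike_id) else NULL,
    rho_final = res$rho_final,
    fake_rho_final = res$fake_rho_final,
    transitions = c(up_to_down = res$up_to_down,
                    down_to_up = res$down_to_up),
    tagged = tagged, rho_init = rho0,
    n_syn = S, net = net, params = p, duration = duration, seed = seed),
    class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat(sprintf("Network run: %g s, %d plastic synapses\n",
              x$duration, x$n_syn))
  cat(sprintf("  mean rate E = %.3g/s, I = %.3g/s\n",
              mean(x$rates$rate_E), mean(x$rates$rate_I)))
  cat(sprintf("  transitions up->down %d, down->up %d\n",
              x$transitions[1], x$transitions[2]))
  invisible(x)
}

#' Memory-implant experiment
#'
#' Initialises the plastic synapses at the theoretically predicted steady
#' state, sets a random subset (default 5%) to `rho = 1` (the implanted
#' memory), runs the network, and fits the exponential decay of the tagged
#' subset mean.  For the flat potential the untagged synapses start at the
#' OU asymptote at `target_rate`; for the double well they start in the
#' DOWN state.
#'
#' @param net a [network_params()] object.
#' @param p a [plasticity_params()] object.
#' @param duration run length (s).
#' @param fraction tagged fraction.
#' @param target_rate rate (spikes/s) used for the steady-state
#'   initialisation of the untagged synapses.
#' @param seed RNG seed.
#' @param trace_dt trace sampling interval (s).
#' @return List with the `network_result` (`run`), the tagged-subset
#'   `decay_fit` (`fit`, flat potential only), and the observed mean
#'   excitatory rate (`rate_E`).
#' @export
memory_implant_experiment <- function(net, p, duration, fraction = 0.05,
                                      target_rate = 1, seed = 1,
                                      trace_dt = 1) {
  base_rho <- if (p$potential == "flat")
    asymptotic_mean(target_rate, target_rate, p) else 0
  run <- simulate_network(net, p, duration, seed = seed,
                          rho_init = base_rho, tag_fraction = fraction,
                          trace_dt = trace_dt, record_raster = FALSE)
  fit <- tryCatch(fit_exponential(
    data.frame(time = run$rho_traces$time,
               mean_rho = run$rho_traces$tagged)),
    error = function(e) NULL)
  list(run = run, fit = fit, rate_E = mean(run$rates$rate_E))
}

#' Independent LIF neurons driven by white noise
#'
#' Disconnected leaky integrate-and-fire neurons receiving the same
#' constant-plus-white-noise drive as the network neurons; used for
#' transfer-function checks and for studying how LIF interspike-interval
#' statistics shape the plasticity (reset-potential experiments).
#'
#' @param n number of neurons.
#' @param duration simulated time (s).
#' @param net a [network_params()] object supplying membrane parameters.
#' @param mu,sigma mean drive above leak and noise amplitude (mV);
#'   default to the external drive in `net`.
#' @param V_r optional reset override (mV).
#' @param seed RNG seed.
#' @return Data frame raster with columns `time`, `neuron`.
#' @export
simulate_lif_neurons <- function(n, duration, net = network_params(),
                                 mu = net$mu_ext, sigma = net$sigma_ext,
                                 V_r = net$V_r, seed = 1) {
  res <- cpp_simulate_lif(as.integer(n), duration, net$tau_m, net$V_L,
                          net$V_th, V_r, mu, sigma, net$dt, seed)
  data.frame(time = res$spike_time, neuron = res$spike_id)
}

#' Interspike-interval statistics of a raster
#'
#' Pools per-neuron interspike intervals, reports the coefficient of
#' variation and the mass of short ISIs compared with the exponential
#' (Poisson) reference at each neuron's own rate.  Short-ISI
#' over-representation (depolarised reset potentials) inflates calcium
#' summation across thresholds and with it the asymptotic efficacy;
#' hyperpolarised resets do the opposite.
#'
#' @param raster data frame with columns `time`, `neuron`.
#' @param short_window width of the "short ISI" window (s).
#' @param min_isis minimum number of pooled ISIs required.
#' @return List with `isi` (pooled), `cv`, `short_mass`,
#'   `expected_short_mass` (Poisson reference), and their `ratio`.
#' @export
isi_statistics <- function(raster, short_window = 0.05, min_isis = 1000L) {
  spl <- split(raster$time, raster$neuron)
  isis <- unlist(lapply(spl, function(tt) if (length(tt) > 1) diff(tt)),
                 use.names = FALSE)
  if (length(isis) < min_isis)
    stop("too few interspike intervals (", length(isis), " < ", min_isis,
         ")")
  cv <- stats::sd(isis) / mean(isis)
  short_mass <- mean(isis <= short_window)
  expected <- mean(unlist(lapply(spl, function(tt) {
    if (length(tt) <= 1) return(NULL)
    rate <- 1 / mean(diff(tt))
    rep(1 - exp(-rate * short_window), length(tt) - 1)
  }), use.names = FALSE))
  list(isi = isis, cv = cv, short_mass = short_mass,
       expected_short_mass = expected, ratio = short_mass / expected)
}
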