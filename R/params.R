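#' Calcium-based plasticity model parameters
#'
#' Container for all constants of the calcium-based synapse model: calcium
#' jump amplitudes, decay time, plasticity thresholds and rates, noise
#' amplitude, efficacy time constant, the barrier position of the double
#' well, and the presynaptic calcium delay.
#'
#' Calcium is dimensionless (the thresholds set its scale).  All times are
#' carried in seconds internally; the constructor accepts the conventional
#' millisecond units for `tau_ca` and `D` via `ms = TRUE` arguments in
#' [ca_preset()].
#'
#' @param C_pre,C_post calcium jump per pre-/postsynaptic spike.
#' @param tau_ca calcium decay time constant (s).
#' @param theta_d,theta_p depression and potentiation thresholds
#'   (`theta_p > theta_d > 0`).
#' @param gamma_d,gamma_p depression and potentiation rates
#'   (`gamma_p > gamma_d > 0`).
#' @param sigma noise amplitude.
#' @param tau_rho efficacy time constant (s).
#' @param rho_star barrier position of the double-well potential (must be
#'   0.5 in double-well mode, where the closed-form subthreshold update is
#'   available).
#' @param D presynaptic calcium delay (s).
#' @param potential `"flat"` or `"double_well"`.
#' @return An object of class `plasticity_params`.
#' @seealso [ca_preset()], [scale_calcium()]
#' @export
plasticity_params <- function(C_pre, C_post, tau_ca, theta_d, theta_p,
                              gamma_d, gamma_p, sigma, tau_rho,
                              rho_star = 0.5, D = 0,
                              potential = c("flat", "double_well")) {
  potential <- match.arg(potential)
  p <- structure(list(
    C_pre = C_pre, C_post = C_post, tau_ca = tau_ca,
    theta_d = theta_d, theta_p = theta_p,
    gamma_d = gamma_d, gamma_p = gamma_p,
    sigma = sigma, tau_rho = tau_rho, rho_star = rho_star, D = D,
    potential = potential
  ), class = "plasticity_params")
  validate_plasticity_params(p)
  p
}

validate_plasticity_params <- function(p) {
  num <- c("C_pre", "C_post", "tau_ca", "theta_d", "theta_p", "gamma_d",
           "gamma_p", "sigma", "tau_rho", "rho_star", "D")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("field '", f, "' must be a finite numeric scalar")
  }
  if (!(p$theta_p > p$theta_d && p$theta_d > 0))
    stop("thresholds must satisfy theta_p > theta_d > 0")
  if (!(p$gamma_p > p$gamma_d && p$gamma_d > 0))
    stop("rates must satisfy gamma_p > gamma_d > 0")
  pos <- c("C_pre", "C_post", "tau_ca", "tau_rho", "sigma")
  for (f in pos) if (p[[f]] <= 0) stop("field '", f, "' must be positive")
  if (p$D < 0) stop("delay D must be nonnegative")
  if (p$rho_star <= 0 || p$rho_star >= 1)
    stop("rho_star must lie strictly between 0 and 1")
  if (p$potential == "double_well" && abs(p$rho_star - 0.5) > 1e-12)
    stop("double-well mode requires rho_star = 0.5 ",
         "(the analytic subthreshold update assumes the symmetric well)")
  invisible(p)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("Calcium-based plasticity parameters (", x$potential, " potential)\n",
      sep = "")
  cat(sprintf("  C_pre = %.5f  C_post = %.5f  tau_ca = %.4f ms  D = %.4f ms\n",
              x$C_pre, x$C_post, 1e3 * x$tau_ca, 1e3 * x$D))
  cat(sprintf("  theta_d = %g  theta_p = %g  gamma_d = %.3f  gamma_p = %.3f\n",
              x$theta_d, x$theta_p, x$gamma_d, x$gamma_p))
  cat(sprintf("  sigma = %.4f  tau_rho = %.4f s  rho_star = %g\n",
              x$sigma, x$tau_rho, x$rho_star))
  invisible(x)
}

#' Published parameter presets
#'
#' The two published parameter sets of the calcium-based synapse model: the
#' `in_vitro` set fitted to cortical slice plasticity data (2.5 mM
#' extracellular calcium), and the `in_vivo` set in which both calcium
#' amplitudes are scaled by 1.5/2.5 = 0.6, the estimated ratio of in-vivo to
#' slice extracellular calcium concentration.  All other constants are
#' shared.
#'
#' @param name `"in_vitro"` or `"in_vivo"`.
#' @param potential `"flat"` or `"double_well"`.
#' @return A [plasticity_params()] object.
#' @examples
#' ca_preset("in_vitro")
#' ca_preset("in_vivo", potential = "double_well")
#' @export
ca_preset <- function(name = c("in_vitro", "in_vivo"),
                      potential = c("flat", "double_well")) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% c("in_vitro", "in_vivo")))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: in_vitro, in_vivo")
  potential <- match.arg(potential)
  amp <- switch(name,
    in_vitro = c(C_pre = 0.56175, C_post = 1.23964),
    in_vivo  = c(C_pre = 0.33705, C_post = 0.74378)
  )
  plasticity_params(
    C_pre = amp[["C_pre"]], C_post = amp[["C_post"]],
    tau_ca = 22.6936e-3,
    theta_d = 1, theta_p = 1.3,
    gamma_d = 331.909, gamma_p = 725.085,
    sigma = 3.3501, tau_rho = 346.3615,
    rho_star = 0.5, D = 4.6098e-3,
    potential = potential
  )
}

#' Scale the calcium amplitudes with extracellular calcium
#'
#' Multiplies the pre- and postsynaptically evoked calcium amplitudes by the
#' ratio of extracellular calcium concentrations, leaving every other
#' parameter untouched.  This is the linear calcium-influx assumption that
#' maps the in-vitro preset onto the in-vivo one (ratio 1.5/2.5 = 0.6).
#'
#' @param p a [plasticity_params()] object.
#' @param ratio positive scale factor for `C_pre` and `C_post`.
#' @return The scaled `plasticity_params` object.
#' @examples
#' p <- scale_calcium(ca_preset("in_vitro"), 0.6)
#' round(p$C_pre, 5)  # 0.33705, the in-vivo value
#' @export
scale_calcium <- function(p, ratio) {
  stopifnot(inherits(p, "plasticity_params"))
  if (!is.numeric(ratio) || length(ratio) != 1L || !is.finite(ratio) ||
      ratio <= 0)
    stop("ratio must be a positive number")
  p$C_pre <- p$C_pre * ratio
  p$C_post <- p$C_post * ratio
  validate_plasticity_params(p)
  p
}

#' Experiment configuration for single-synapse ensembles
#'
#' @param nu_pre,nu_post pre- and postsynaptic Poisson rates (spikes/s).
#' @param duration simulated time (s).
#' @param n_synapses ensemble size.
#' @param seed RNG seed (integer).
#' @param rho_init initial efficacy.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(nu_pre, nu_post, duration, n_synapses = 1L,
                              seed = 1L, rho_init = 1) {
  if (nu_pre < 0 || nu_post < 0) stop("rates must be nonnegative")
  if (duration <= 0) stop("duration must be positive")
  if (n_synapses < 1) stop("n_synapses must be at least 1")
  structure(list(nu_pre = nu_pre, nu_post = nu_post, duration = duration,
                 n_synapses = as.integer(n_synapses), seed = as.integer(seed),
                 rho_init = rho_init),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "Experiment: nu_pre = %g/s, nu_post = %g/s, %g s, n = %d, seed = %d, rho0 = %g\n",
    x$nu_pre, x$nu_post, x$duration, x$n_synapses, x$seed, x$rho_init))
  invisible(x)
}
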