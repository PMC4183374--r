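#' Siegert transfer function of the LIF neuron
#'
#' Stationary firing rate of a leaky integrate-and-fire neuron driven by
#' white noise with mean `mu` (measured from the leak potential, mV) and
#' amplitude `sigma` (mV), with zero refractory period:
#' \deqn{\nu = \left[\tau_m \sqrt{\pi}
#'   \int_{(V_r-V_L-\mu)/\sigma}^{(V_{th}-V_L-\mu)/\sigma}
#'   e^{u^2} (1 + \mathrm{erf}(u)) \, du\right]^{-1}.}
#' The integrand is evaluated as `erfcx(-u)` (scaled complementary error
#' function), which stays finite where the raw form overflows; for deeply
#' subthreshold drive the rate underflows to zero.
#'
#' @param mu mean input above leak (mV).
#' @param sigma noise amplitude (mV), positive.
#' @param tau_m membrane time constant (s).
#' @param V_th,V_r,V_L threshold, reset and leak potentials (mV).
#' @return Firing rate (spikes/s).
#' @examples
#' siegert_rate(10, 5, 20e-3, -50, -60, -70)
#' @export
siegert_rate <- function(mu, sigma, tau_m, V_th, V_r, V_L = -70) {
  if (sigma <= 0)
    stop("sigma must be positive (deterministic LIF not supported)")
  lb <- (V_r - V_L - mu) / sigma
  ub <- (V_th - V_L - mu) / sigma
  if (ub > 25) return(0)  # rate below ~1e-260/s
  ig <- function(u) pracma::erfcx(-u)
  val <- stats::integrate(ig, lb, ub, rel.tol = 1e-10,
                          abs.tol = 0)$value
  1 / (tau_m * sqrt(pi) * val)
}

#' Self-consistent mean-field solution of the network steady state
#'
#' Solves the three coupled equations of the recurrent network's fixed
#' point: the stationary rates of both populations from the Siegert
#' transfer function with input moments
#' \deqn{\mu_\alpha = \mu_{ext} + \tau_m (C_E J_{\alpha E} \bar w \nu_E
#'       + C_I J_{\alpha I} \nu_I)}
#' \deqn{\sigma_\alpha^2 = \sigma_{ext}^2 + \tau_m
#'       (C_E J_{\alpha E}^2 \bar w^2_{rel} \nu_E + C_I J_{\alpha I}^2
#'       \nu_I)}
#' (with mean E-to-E weight `J_EE_max * rho_bar`, `C` the expected
#' in-degrees), and the mean E-to-E efficacy `rho_bar` from the
#' truncated-OU asymptote at the excitatory rate, assuming Poisson firing.
#' Damped fixed-point iteration (factor 0.5 on the rate updates).
#'
#' @param net a [network_params()] object.
#' @param p a [plasticity_params()] object.
#' @param init named list or vector with starting `nu_E`, `nu_I`, and
#'   optionally `rho_bar`.
#' @param damping damping factor on rate updates in (0, 1].
#' @param tol convergence tolerance on the self-consistency residual.
#' @param max_iter iteration cap.
#' @return Object of class `meanfield_solution` with `nu_E`, `nu_I`,
#'   `rho_bar`, the input moments, and the final `residual`.
#' @export
solve_meanfield <- function(net, p, init = c(nu_E = 1, nu_I = 1),
                            damping = 0.5, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(net, "network_params"),
            inherits(p, "plasticity_params"))
  CE <- net$p_conn * net$N_E
  CI <- net$p_conn * net$N_I
  nuE <- init[["nu_E"]]
  nuI <- init[["nu_I"]]
  rb <- if ("rho_bar" %in% names(init)) init[["rho_bar"]] else 0.2
  if (nuE <= 0 || nuI <= 0) stop("initial rates must be positive")

  moments <- function(nuE, nuI, rb) {
    wEE <- net$J_EE_max * rb
    muE <- net$mu_ext + net$tau_m * (CE * wEE * nuE + CI * net$J_EI * nuI)
    muI <- net$mu_ext + net$tau_m * (CE * net$J_IE * nuE +
                                       CI * net$J_II * nuI)
    sgE <- sqrt(net$sigma_ext^2 +
                  net$tau_m * (CE * wEE^2 * nuE + CI * net$J_EI^2 * nuI))
    sgI <- sqrt(net$sigma_ext^2 +
                  net$tau_m * (CE * net$J_IE^2 * nuE +
                                 CI * net$J_II^2 * nuI))
    list(muE = muE, muI = muI, sgE = sgE, sgI = sgI)
  }
  # cache the efficacy asymptote: the alpha pipeline is the costly part
  rho_cache <- new.env(parent = emptyenv())
  rho_of <- function(nu) {
    key <- sprintf("%.6e", nu)
    if (!is.null(rho_cache[[key]])) return(rho_cache[[key]])
    v <- asymptotic_mean(nu, nu, p)
    rho_cache[[key]] <- v
    v
  }

  residual <- Inf
  for (it in seq_len(max_iter)) {
    m <- moments(nuE, nuI, rb)
    nuE_new <- siegert_rate(m$muE, m$sgE, net$tau_m, net$V_th, net$V_r,
                            net$V_L)
    nuI_new <- siegert_rate(m$muI, m$sgI, net$tau_m, net$V_th, net$V_r,
                            net$V_L)
    rb_new <- if (nuE_new > 1e-6) rho_of(max(nuE_new, 1e-4)) else rb
    residual <- max(abs(nuE_new - nuE), abs(nuI_new - nuI),
                    abs(rb_new - rb))
    nuE <- (1 - damping) * nuE + damping * nuE_new
    nuI <- (1 - damping) * nuI + damping * nuI_new
    rb <- (1 - damping) * rb + damping * rb_new
    if (residual < tol) break
  }
  if (residual >= tol)
    stop("mean-field iteration did not converge: residual ",
         signif(residual, 3), " after ", max_iter, " iterations ",
         "(nu_E ~ ", signif(nuE, 4), ", nu_I ~ ", signif(nuI, 4), ")")
  m <- moments(nuE, nuI, rb)
  structure(list(nu_E = nuE, nu_I = nuI, rho_bar = rb,
                 mu_E = m$muE, mu_I = m$muI,
                 sigma_E = m$sgE, sigma_I = m$sgI,
                 residual = residual, iterations = it),
            class = "meanfield_solution")
}

#' @export
print.meanfield_solution <- function(x, ...) {
  cat(sprintf(
    "Mean-field fixed point: nu_E = %.4g/s, nu_I = %.4g/s, rho_bar = %.4g\n",
    x$nu_E, x$nu_I, x$rho_bar))
  cat(sprintf("  mu_E = %.3g mV (sd %.3g), mu_I = %.3g mV (sd %.3g); residual %.2g\n",
              x$mu_E, x$sigma_E, x$mu_I, x$sigma_I, x$residual))
  invisible(x)
}
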