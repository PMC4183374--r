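#' Truncated Ornstein-Uhlenbeck summary of flat-potential decay
#'
#' Under background Poisson firing the flat-potential efficacy is, in the
#' diffusion approximation, an Ornstein-Uhlenbeck process truncated to
#' `[0, 1]`.  Its ingredients are the net rates
#' `Gamma_p = gamma_p alpha_p` and `Gamma_d = gamma_d alpha_d` (with the
#' alpha fractions from the stationary calcium density), giving
#' * decay time constant `tau_eff = tau_rho / (Gamma_p + Gamma_d)`,
#' * unbounded asymptote `rho_bar_unbounded = Gamma_p / (Gamma_p+Gamma_d)`,
#' * stationary standard deviation
#'   `sd = sigma sqrt((alpha_d + alpha_p) / (2 (Gamma_p + Gamma_d)))`,
#' * truncated-Gaussian asymptotic mean `rho_bar` on `[0, 1]`.
#'
#' @param nu_pre,nu_post Poisson rates (spikes/s).
#' @param p a [plasticity_params()] object.
#' @param hdiv grid resolution passed to [ca_stationary_pdf()].
#' @return Object of class `ou_summary`.
#' @examples
#' ou_summary(1, 1, ca_preset("in_vitro"))
#' @export
ou_summary <- function(nu_pre, nu_post, p, hdiv = 400L) {
  stopifnot(inherits(p, "plasticity_params"))
  al <- alpha_fractions(nu_pre, nu_post, p, hdiv = hdiv)
  Gp <- p$gamma_p * al[["alpha_p"]]
  Gd <- p$gamma_d * al[["alpha_d"]]
  Gsum <- Gp + Gd
  tau_eff <- if (Gsum > 0) p$tau_rho / Gsum else Inf
  if (Gsum > 0) {
    mu <- Gp / Gsum
    sdst <- p$sigma * sqrt((al[["alpha_d"]] + al[["alpha_p"]]) / (2 * Gsum))
    rho_bar <- truncated_gaussian_mean(mu, sdst)
  } else {
    mu <- NA_real_
    sdst <- 0
    rho_bar <- NA_real_
  }
  structure(list(Gamma_p = Gp, Gamma_d = Gd, tau_eff = tau_eff,
                 rho_bar = rho_bar, rho_bar_unbounded = mu,
                 sd_stationary = sdst,
                 alpha_d = al[["alpha_d"]], alpha_p = al[["alpha_p"]],
                 nu_pre = nu_pre, nu_post = nu_post),
            class = "ou_summary")
}

#' @export
print.ou_summary <- function(x, ...) {
  cat("Truncated-OU summary\n")
  cat(sprintf("  Gamma_p = %.5g  Gamma_d = %.5g\n", x$Gamma_p, x$Gamma_d))
  cat(sprintf("  tau_eff = %.5g s  rho_bar = %.4g (unbounded %.4g)  sd = %.4g\n",
              x$tau_eff, x$rho_bar, x$rho_bar_unbounded, x$sd_stationary))
  invisible(x)
}

# mean of a Gaussian(mu, sd) truncated to [0, 1]
truncated_gaussian_mean <- function(mu, sd) {
  if (sd <= 0) return(min(max(mu, 0), 1))
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  den <- stats::pnorm(b) - stats::pnorm(a)
  if (den < 1e-300) return(min(max(mu, 0), 1))
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / den
}

#' Exponential decay time constant of the mean efficacy
#'
#' `tau_eff = tau_rho / (gamma_p alpha_p + gamma_d alpha_d)`, the time
#' constant of the exponential decay of the mean flat-potential efficacy
#' under background firing.  Returns `Inf` when no plasticity is induced
#' (both alpha fractions zero).
#'
#' @inheritParams ou_summary
#' @return Decay time constant (s).
#' @examples
#' decay_time_constant(1, 1, ca_preset("in_vitro"))  # about 150 s
#' @export
decay_time_constant <- function(nu_pre, nu_post, p, hdiv = 400L) {
  ou_summary(nu_pre, nu_post, p, hdiv = hdiv)$tau_eff
}

#' Asymptotic mean efficacy of the truncated OU process
#'
#' The mean around which the flat-potential efficacy eventually fluctuates:
#' the mean of the stationary Gaussian truncated to `[0, 1]`.  At high
#' rates (`alpha_d, alpha_p -> 1`) it saturates at
#' `gamma_p / (gamma_p + gamma_d)`.
#'
#' @inheritParams ou_summary
#' @return Asymptotic mean efficacy in `[0, 1]`.
#' @examples
#' asymptotic_mean(1, 1, ca_preset("in_vitro"))  # about 0.2
#' @export
asymptotic_mean <- function(nu_pre, nu_post, p, hdiv = 400L) {
  s <- ou_summary(nu_pre, nu_post, p, hdiv = hdiv)
  if (s$Gamma_p + s$Gamma_d <= 0)
    stop("asymptotic mean undefined: zero net plasticity rate")
  s$rho_bar
}

#' Mean efficacy trajectory of the truncated OU theory
#'
#' `rho(t) = rho_bar + (rho0 - rho_bar) exp(-t / tau_eff)`.
#'
#' @param rho0 initial efficacy.
#' @param t time points (s), nonnegative.
#' @param summary an [ou_summary()] object.
#' @return Numeric vector of mean efficacies.
#' @export
mean_trajectory <- function(rho0, t, summary) {
  stopifnot(inherits(summary, "ou_summary"))
  if (any(t < 0)) stop("t must be nonnegative")
  summary$rho_bar + (rho0 - summary$rho_bar) * exp(-t / summary$tau_eff)
}

#' Low-rate power law of the memory time scale
#'
#' At low rates the decay time constant scales as `tau_eff ~ nu^-k`, where
#' `k` is the number of simultaneous spikes needed to cross the depression
#' threshold.  Fits the log-log slope of `tau_eff(nu)` over a rate grid and
#' returns it together with `k` from [min_spikes_to_cross()].
#'
#' @param p a [plasticity_params()] object.
#' @param nu_grid increasing grid of (equal pre/post) rates spanning at
#'   least one decade.
#' @param hdiv PDF grid resolution.
#' @return List with `k`, `slope` (fitted, ideally close to `-k`), and the
#'   data frame `fit` of rates and time constants.
#' @export
low_rate_power_law <- function(p, nu_grid, hdiv = 400L) {
  stopifnot(inherits(p, "plasticity_params"))
  nu_grid <- sort(unique(nu_grid))
  if (length(nu_grid) < 3 || max(nu_grid) / min(nu_grid) < 10 * 0.999 ||
      min(nu_grid) <= 0)
    stop("nu_grid must contain >= 3 positive rates spanning >= 1 decade")
  taus <- vapply(nu_grid, function(nu)
    decay_time_constant(nu, nu, p, hdiv = hdiv), numeric(1))
  fit <- stats::lm(log(taus) ~ log(nu_grid))
  list(k = min_spikes_to_cross(p, p$theta_d),
       slope = unname(stats::coef(fit)[2]),
       fit = data.frame(nu = nu_grid, tau_eff = taus))
}
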