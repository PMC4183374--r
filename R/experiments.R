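#' Fit a single exponential decay to a mean efficacy trace
#'
#' Least-squares fit of `rho(t) = a + b exp(-t / tau)` to a time-binned
#' ensemble-mean trace, the convention used to extract decay time
#' constants from simulations.  Starting values come from the tail mean
#' (plateau) and a log-linear fit of the excess above it; the nonlinear
#' refinement uses Levenberg-Marquardt.
#'
#' @param trace data frame with columns `time` and `mean_rho` (or `rho`).
#' @return Object of class `decay_fit` with `tau_fit` (s), `asymptote_fit`,
#'   `rho0_fit` (value at t = 0), and `residual_rms`.
#' @examples
#' t <- seq(0, 900, by = 5)
#' tr <- data.frame(time = t, mean_rho = 0.2 + 0.8 * exp(-t / 150))
#' fit_exponential(tr)
#' @export
fit_exponential <- function(trace) {
  rho <- if ("mean_rho" %in% names(trace)) trace$mean_rho else trace$rho
  t <- trace$time
  if (length(t) < 10) stop("trace must have at least 10 points")
  if (stats::sd(rho) < 1e-12)
    stop("constant trace: no decay to fit")
  n <- length(t)
  a0 <- mean(rho[t >= stats::quantile(t, 0.8)])
  b0 <- rho[1] - a0
  if (abs(b0) < 1e-12) b0 <- rho[1] - mean(rho)
  excess <- (rho - a0) / b0
  ok <- excess > 1e-3
  tau0 <- if (sum(ok) >= 3) {
    fitl <- stats::lm(log(excess[ok]) ~ t[ok])
    max(-1 / stats::coef(fitl)[2], diff(range(t)) / 100)
  } else diff(range(t)) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(t)) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(rho ~ a + b * exp(-t / tau),
                      start = list(a = a0, b = b0, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e),
                             " [start a=", signif(a0, 3), " b=",
                             signif(b0, 3), " tau=", signif(tau0, 3), "]"))
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(list(tau_fit = unname(cf["tau"]),
                 asymptote_fit = unname(cf["a"]),
                 rho0_fit = unname(cf["a"] + cf["b"]),
                 residual_rms = sqrt(mean(res^2)),
                 n_points = n),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit: tau = %.4g s, asymptote = %.4g, rho0 = %.4g (rms %.3g)\n",
    x$tau_fit, x$asymptote_fit, x$rho0_fit, x$residual_rms))
  invisible(x)
}

#' Ensemble decay experiment with theory overlay
#'
#' Runs an ensemble of Poisson-driven synapses, fits the single-exponential
#' decay of its mean, and reports it next to the truncated-OU prediction.
#'
#' @param config an [experiment_config()] object.
#' @param p a [plasticity_params()] object.
#' @param bin_dt trace bin width (s); defaults to a fiftieth of the
#'   theoretical time constant.
#' @return List with `trace`, `fit` (a `decay_fit`), `theory` (an
#'   [ou_summary()]), and `final_rho`.
#' @export
run_decay_experiment <- function(config, p, bin_dt = NULL) {
  theory <- ou_summary(config$nu_pre, config$nu_post, p)
  if (is.null(bin_dt)) {
    bin_dt <- if (is.finite(theory$tau_eff)) theory$tau_eff / 50 else
      config$duration / 200
    bin_dt <- min(max(bin_dt, 0.1), config$duration / 20)
  }
  sim <- run_ensemble(config, p, bin_dt = bin_dt)
  fit <- fit_exponential(sim$trace)
  list(trace = sim$trace, fit = fit, theory = theory,
       final_rho = sim$final_rho)
}

#' Mean UP-state dwell time with censoring
#'
#' Exponential maximum-likelihood estimate of the mean first-passage time
#' from the UP state through the barrier, using censored observations:
#' `T_hat = (total observed time) / (number of crossings)`.  With zero
#' crossings but censored runs the estimate is infinite (a lower bound of
#' total time is reported); with no data at all this errors.
#'
#' @param fp data frame from [simulate_first_passage()] with columns
#'   `time` and `censored`.
#' @return List with `mean_dwell` (s), `n_events`, `n_censored`, and
#'   `total_time`.
#' @export
dwell_time_stats <- function(fp) {
  if (is.null(fp$time) || length(fp$time) == 0)
    stop("no crossings and no censoring information: cannot estimate ",
         "the dwell time")
  n_events <- sum(!fp$censored)
  total <- sum(fp$time)
  mean_dwell <- if (n_events > 0) total / n_events else Inf
  list(mean_dwell = mean_dwell, n_events = n_events,
       n_censored = sum(fp$censored), total_time = total)
}
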