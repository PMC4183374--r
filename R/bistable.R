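#' Effective potential of a bistable synapse under background activity
#'
#' Background firing adds two quadratic terms to the bare double-well
#' potential, giving the effective potential
#' \deqn{U_{eff}(\rho) = \frac{\rho^2 (1-\rho)^2}{4}
#'   + \frac{\Gamma_d}{2} \rho^2 + \frac{\Gamma_p}{2} (1-\rho)^2}
#' with the net rates `Gamma_d = gamma_d alpha_d`,
#' `Gamma_p = gamma_p alpha_p`.  The depression term deepens the DOWN well
#' at the expense of the UP well; the potentiation term pulls the remaining
#' minimum toward `gamma_p/(gamma_p+gamma_d)`.  The effective noise
#' amplitude is `sigma_eff = sigma sqrt(alpha_d + alpha_p)`.
#'
#' Fixed points are located by a dense sign scan of `dU_eff/drho` over
#' `[-0.2, 1.2]` (2000 points) refined by bisection; away from the
#' saddle-node bifurcation their count is 1 or 3.
#'
#' @param nu firing rate (spikes/s), common to pre and post.
#' @param p a [plasticity_params()] object with `potential = "double_well"`.
#' @param sigma_scale noise multiplier applied to `sigma_eff` (fixed points
#'   are noise-independent).
#' @param hdiv PDF grid resolution.
#' @return Object of class `effective_landscape` with fields `nu`, `U_eff`
#'   (callable), `dU_eff`, `sigma_eff`, `fixed_points`, `barrier_dU`
#'   (UP-well barrier, `NA` if monostable) and `T_escape` (Kramers time,
#'   `NA` if monostable).
#' @examples
#' L <- effective_potential(1, ca_preset("in_vivo", "double_well"))
#' L$fixed_points
#' @export
effective_potential <- function(nu, p, sigma_scale = 1, hdiv = 400L) {
  stopifnot(inherits(p, "plasticity_params"))
  if (p$potential != "double_well")
    stop("effective potential analysis requires the double-well potential")
  if (nu < 0) stop("rate must be nonnegative")
  al <- if (nu > 0) alpha_fractions(nu, nu, p, hdiv = hdiv) else
    c(alpha_d = 0, alpha_p = 0)
  Gd <- p$gamma_d * al[["alpha_d"]]
  Gp <- p$gamma_p * al[["alpha_p"]]
  sig_eff <- p$sigma * sigma_scale *
    sqrt(al[["alpha_d"]] + al[["alpha_p"]])
  U <- function(x) x^2 * (1 - x)^2 / 4 + Gd / 2 * x^2 + Gp / 2 * (1 - x)^2
  dU <- function(x) x * (1 - x) * (0.5 - x) + Gd * x - Gp * (1 - x)
  d2U <- function(x) 0.5 - 3 * x + 3 * x^2 + Gd + Gp

  # dense scan + bisection
  xs <- seq(-0.2, 1.2, length.out = 2000)
  dv <- dU(xs)
  roots <- numeric(0)
  for (i in seq_len(length(xs) - 1)) {
    if (dv[i] == 0) roots <- c(roots, xs[i])
    else if (dv[i] * dv[i + 1] < 0) {
      lo <- xs[i]; hi <- xs[i + 1]
      for (j in 1:60) {
        mid <- (lo + hi) / 2
        if (dU(lo) * dU(mid) <= 0) hi <- mid else lo <- mid
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  roots <- sort(roots)

  barrier <- NA_real_
  T_escape <- NA_real_
  if (length(roots) >= 3) {
    r <- roots[1:3]
    up <- r[3]; saddle <- r[2]
    barrier <- U(saddle) - U(up)
    if (barrier >= 0 && sig_eff > 0) {
      pref <- 2 * pi * p$tau_rho / sqrt(d2U(up) * abs(d2U(saddle)))
      T_escape <- pref * exp(2 * barrier / sig_eff^2)
    }
  }
  structure(list(nu = nu, U_eff = U, dU_eff = dU, d2U_eff = d2U,
                 Gamma_p = Gp, Gamma_d = Gd, sigma_eff = sig_eff,
                 alpha_d = al[["alpha_d"]], alpha_p = al[["alpha_p"]],
                 fixed_points = roots, barrier_dU = barrier,
                 T_escape = T_escape),
            class = "effective_landscape")
}

#' @export
print.effective_landscape <- function(x, ...) {
  cat(sprintf("Effective landscape at nu = %g/s\n", x$nu))
  cat("  fixed points:", paste(sprintf("%.4f", x$fixed_points),
                               collapse = ", "), "\n")
  cat(sprintf("  sigma_eff = %.5g  barrier = %.5g  T_escape = %.5g s\n",
              x$sigma_eff, x$barrier_dU, x$T_escape))
  invisible(x)
}

#' Saddle-node bifurcation rate of the effective potential
#'
#' The firing rate at which the high-efficacy minimum of the effective
#' potential disappears (fixed-point count drops from 3 to 1), found by
#' bisection with root counting.  Fixed points do not depend on the noise
#' amplitude.
#'
#' @param p a [plasticity_params()] object (double-well).
#' @param lower,upper bracketing rates (spikes/s); the landscape must be
#'   bistable at `lower`.
#' @param tol bisection tolerance on the rate (spikes/s).
#' @param hdiv PDF grid resolution.
#' @return Critical rate `nu_c` (spikes/s).
#' @examples
#' \donttest{
#' bifurcation_rate(ca_preset("in_vivo", "double_well"))  # about 1.3/s
#' }
#' @export
bifurcation_rate <- function(p, lower = 5e-3, upper = 20, tol = 1e-3,
                             hdiv = 400L) {
  stopifnot(inherits(p, "plasticity_params"))
  nfix <- function(nu)
    length(effective_potential(nu, p, hdiv = hdiv)$fixed_points)
  if (nfix(lower) < 3)
    stop("no bistability at the lower bracket rate; the double well is ",
         "already destroyed at nu = ", lower, "/s")
  if (nfix(upper) >= 3)
    stop("still bistable at the upper bracket rate; increase 'upper'")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nfix(mid) >= 3) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Kramers escape time from the UP state
#'
#' Mean escape time over the effective potential barrier,
#' \deqn{T = \frac{2\pi \tau_\rho}
#'   {\sqrt{U_{eff}''(\rho_{min}) |U_{eff}''(\rho_{saddle})|}}
#'   \exp\!\left(\frac{2 \Delta U}{\sigma_{eff}^2}\right)}
#' with `Delta U` the barrier height seen from the UP minimum.  `ln T`
#' grows as `sigma_eff^-2 Delta U`; at low rates this makes the memory
#' time scale increase exponentially with the inverse rate to the power
#' `k` (the number of spikes needed to cross the depression threshold).
#'
#' @inheritParams effective_potential
#' @return Escape time (s).
#' @examples
#' \donttest{
#' kramers_escape_time(1, ca_preset("in_vivo", "double_well"))  # ~ a month
#' }
#' @export
kramers_escape_time <- function(nu, p, sigma_scale = 1, hdiv = 400L) {
  L <- effective_potential(nu, p, sigma_scale = sigma_scale, hdiv = hdiv)
  if (length(L$fixed_points) < 3)
    stop("monostable regime at nu = ", nu,
         "/s: no barrier to escape; use decay_time_constant() instead")
  L$T_escape
}

#' Stationary efficacy distribution under background firing
#'
#' Stationary distribution of the efficacy used for CDF reverse-lookup
#' initialisation: for the flat potential, the truncated Gaussian of the
#' OU theory; for the double well, the Fokker-Planck stationary density
#' `p(rho) ~ exp(-2 U_eff(rho) / sigma_eff^2)` on `[0, 1]`.
#'
#' @param nu firing rate (spikes/s), pre = post.
#' @param p a [plasticity_params()] object.
#' @param n_grid grid points on `[0, 1]`.
#' @return List with `grid`, `pdf`, `cdf`.
#' @export
stationary_efficacy_dist <- function(nu, p, n_grid = 2001L) {
  stopifnot(inherits(p, "plasticity_params"))
  grid <- seq(0, 1, length.out = n_grid)
  if (p$potential == "flat") {
    s <- ou_summary(nu, nu, p)
    if (s$sd_stationary <= 0) stop("degenerate stationary distribution")
    w <- stats::dnorm(grid, s$rho_bar_unbounded, s$sd_stationary)
  } else {
    L <- effective_potential(nu, p)
    if (L$sigma_eff <= 0) stop("degenerate stationary distribution")
    lw <- -2 * L$U_eff(grid) / L$sigma_eff^2
    w <- exp(lw - max(lw))
  }
  Z <- pracma::trapz(grid, w)
  pdf <- w / Z
  cdf <- cumsum(c(0, 0.5 * (pdf[-1] + pdf[-n_grid]) * diff(grid)))
  cdf <- cdf / cdf[n_grid]
  list(grid = grid, pdf = pdf, cdf = cdf)
}

#' Sample efficacies by CDF reverse lookup
#'
#' @inheritParams stationary_efficacy_dist
#' @param n number of samples.
#' @param seed RNG seed (uses and restores R's RNG state).
#' @return Numeric vector of sampled efficacies.
#' @export
sample_stationary_rho <- function(n, nu, p, seed = 1, n_grid = 2001L) {
  d <- stationary_efficacy_dist(nu, p, n_grid = n_grid)
  u <- with_local_seed(seed, stats::runif(n))
  # reverse lookup of the CDF
  ii <- findInterval(u, d$cdf, all.inside = TRUE)
  x0 <- d$grid[ii]; x1 <- d$grid[ii + 1]
  c0 <- d$cdf[ii]; c1 <- d$cdf[ii + 1]
  w <- ifelse(c1 > c0, (u - c0) / (c1 - c0), 0.5)
  x0 + w * (x1 - x0)
}
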