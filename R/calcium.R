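#' Decay-and-jump update of the calcium concentration
#'
#' Exact event update of the calcium shot-noise process: exponential decay
#' from the time of the last update followed by an instantaneous jump.
#' Presynaptic events are expected to be enqueued at spike time + D before
#' reaching this operation; postsynaptic events at spike time.
#'
#' @param state list with fields `c` (calcium) and `t_last` (s).
#' @param t_event event time (s), not before `state$t_last`.
#' @param amplitude nonnegative jump amplitude.
#' @param tau_ca calcium decay time constant (s).
#' @return Updated state list.
#' @export
ca_decay_jump <- function(state, t_event, amplitude, tau_ca) {
  if (t_event < state$t_last)
    stop("event ordering violated: t_event precedes the last update")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  c_new <- state$c * exp(-(t_event - state$t_last) / tau_ca) + amplitude
  list(c = c_new, t_last = t_event)
}

#' Threshold-crossing partition of an inter-event interval
#'
#' Splits an interval of length `dt`, over which calcium decays
#' exponentially from `c0`, into the durations spent above the potentiation
#' threshold, between the two thresholds, and below the depression
#' threshold.  The six possible crossing cases are exactly the sign
#' patterns of the crossing times `tau_ca * log(c0 / theta)` clipped to
#' `[0, dt]`.
#'
#' @param c0 calcium at the start of the interval (after the last jump).
#' @param dt interval length (s), nonnegative.
#' @param tau_ca calcium decay time (s).
#' @param theta_d,theta_p depression and potentiation thresholds.
#' @return List with `t_above_p`, `t_between`, `t_below` (summing to `dt`)
#'   and `case` (Roman numeral I-VI).
#' @export
threshold_partition <- function(c0, dt, tau_ca, theta_d, theta_p) {
  if (dt < 0) stop("dt must be nonnegative")
  if (c0 < 0) stop("calcium must be nonnegative")
  t_d <- if (c0 > theta_d) min(dt, tau_ca * log(c0 / theta_d)) else 0
  t_p <- if (c0 > theta_p) min(dt, tau_ca * log(c0 / theta_p)) else 0
  t_between <- t_d - t_p
  t_below <- dt - t_d
  case <- if (c0 > theta_p) {
    if (t_p >= dt) "I" else if (t_d >= dt) "II" else "III"
  } else if (c0 > theta_d) {
    if (t_d >= dt) "IV" else "V"
  } else "VI"
  list(t_above_p = t_p, t_between = t_between, t_below = t_below,
       case = case)
}

#' Stationary calcium density (numeric master-equation solver)
#'
#' Solves the stationary master equation of the two-amplitude calcium shot
#' noise under independent pre- and postsynaptic Poisson firing.  The
#' stationary flux balance
#' \deqn{(c/\tau_{Ca}) p(c) = \nu_{pre}[F(c) - F(c - C_{pre})] +
#'       \nu_{post}[F(c) - F(c - C_{post})]}
#' is integrated forward in `c` from 0: on the first panel
#' `(0, min(C_pre, C_post)]` the solution is the exact power law
#' `F(c) = K c^a` with `a = (nu_pre + nu_post) tau_ca` (an integrable
#' divergence of the density at low rates, kept analytically rather than on
#' the grid), and beyond it the lagged ordinary differential equation is
#' integrated by RK4.  The delay D plays no role here: a Poisson process
#' shifted by a constant is Poisson, so stationary statistics are
#' unaffected for independent inputs.
#'
#' @param nu_pre,nu_post Poisson rates (spikes/s).
#' @param p a [plasticity_params()] object.
#' @param hdiv grid steps per smallest calcium amplitude (resolution).
#' @param cmax upper end of the integration range; chosen automatically
#'   from the shot-noise mean and variance when `NULL`.
#' @return Object of class `calcium_pdf` with the evaluation grid, the
#'   normalised density and CDF, the normalisation constant `Z` of the raw
#'   solution, the probability mass below the first jump scale
#'   (`point_mass`), and the fractions of time `alpha_d`, `alpha_p` spent
#'   above the two thresholds.
#' @examples
#' pdf <- ca_stationary_pdf(1, 1, ca_preset("in_vitro"))
#' c(pdf$alpha_d, pdf$alpha_p)
#' @export
ca_stationary_pdf <- function(nu_pre, nu_post, p, hdiv = 400L, cmax = NULL) {
  stopifnot(inherits(p, "plasticity_params"))
  if (nu_pre < 0 || nu_post < 0) stop("rates must be nonnegative")
  if (hdiv < 20)
    stop("grid too coarse to resolve the smallest calcium amplitude; ",
         "increase hdiv (>= 20, default 400)")
  if (nu_pre + nu_post == 0) {
    out <- structure(list(
      grid = 0, density = Inf, cdf = 1, Z = 1, point_mass = 1,
      a_exponent = 0, alpha_d = 0, alpha_p = 0,
      nu_pre = nu_pre, nu_post = nu_post, params = p,
      method = "degenerate"), class = "calcium_pdf")
    return(out)
  }
  res <- cpp_ca_pdf(nu_pre, nu_post, p$C_pre, p$C_post, p$tau_ca,
                    p$theta_d, p$theta_p, as.integer(hdiv),
                    if (is.null(cmax)) -1 else cmax)
  structure(list(
    grid = res$grid,
    density = res$density_raw / res$Z,
    cdf = res$cdf_raw / res$Z,
    Z = res$Z,
    point_mass = res$cdf_raw[1] / res$Z,  # mass below c_min (analytic panel)
    c_min = res$c_min,
    a_exponent = res$a_exponent,
    alpha_d = res$alpha_d, alpha_p = res$alpha_p,
    nu_pre = nu_pre, nu_post = nu_post, params = p,
    method = "master_equation"), class = "calcium_pdf")
}

#' @export
print.calcium_pdf <- function(x, ...) {
  cat("Stationary calcium PDF (", x$method, ")\n", sep = "")
  cat(sprintf("  nu_pre = %g/s, nu_post = %g/s\n", x$nu_pre, x$nu_post))
  cat(sprintf("  alpha_d = %.6g, alpha_p = %.6g, mass below first jump = %.4g\n",
              x$alpha_d, x$alpha_p, x$point_mass))
  invisible(x)
}

#' Evaluate a stationary calcium density
#'
#' @param pdf a `calcium_pdf` object.
#' @param c_values calcium values at which to evaluate the normalised
#'   density.
#' @return Numeric vector of densities.
#' @export
ca_pdf_density <- function(pdf, c_values) {
  stopifnot(inherits(pdf, "calcium_pdf"))
  if (identical(pdf$method, "degenerate"))
    return(ifelse(c_values == 0, Inf, 0))
  a <- pdf$a_exponent
  cmin <- pdf$c_min
  out <- numeric(length(c_values))
  inner <- c_values > 0 & c_values <= cmin
  # analytic panel: p(c) = a c^{a-1} / (cmin^a Z)
  out[inner] <- a * c_values[inner]^(a - 1) / (cmin^a * pdf$Z)
  outer_i <- c_values > cmin
  out[outer_i] <- stats::approx(pdf$grid, pdf$density, c_values[outer_i],
                                rule = 2)$y
  out
}

#' Stationary calcium density, equal-amplitude closed form
#'
#' For the special case `C_pre = C_post = C` the stationary density has a
#' piecewise analytic form in `x = c/C` with `a = nu_tot * tau_ca`:
#' `F(x) = K x^a` on the first panel, and on the second panel
#' `F(x) = K x^a [1 - a S(1 - 1/x)]` where
#' `S(w) = sum_{m>=0} w^(a+1+m)/(a+1+m)` is the incomplete-beta series,
#' equivalently `w^(a+1)/(a+1) * 2F1(1, a+1; a+2; w)` with the ordinary
#' hypergeometric function.  Later panels are continued with the exact
#' integrating-factor recursion
#' `F(x) = x^a [F(n) n^-a - a Int_n^x F(u-1) u^(-a-1) du]`
#' evaluated by composite quadrature; this is an independent computational
#' route from the numeric master-equation solver.
#'
#' @param nu total Poisson rate (spikes/s), i.e. `nu_pre + nu_post`.
#' @param C common jump amplitude.
#' @param tau_ca calcium decay time (s).
#' @param theta_d,theta_p thresholds at which the time fractions are
#'   reported.
#' @param xmax upper end of the range in units of `C`.
#' @param m grid points per panel for the continuation.
#' @param params optionally a [plasticity_params()] object supplying the
#'   amplitude, decay time and thresholds; an error points to the numeric
#'   solver if its two amplitudes differ.
#' @return Object of class `calcium_pdf` (method `"closed_form"`).
#' @export
ca_stationary_pdf_closed <- function(nu, C, tau_ca, theta_d = 1,
                                     theta_p = 1.3, xmax = NULL,
                                     m = 2000L, params = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "plasticity_params"))
    if (abs(params$C_pre - params$C_post) > 1e-12)
      stop("closed form requires equal calcium amplitudes ",
           "(C_pre = C_post); use the numeric solver ca_stationary_pdf()")
    C <- params$C_pre
    tau_ca <- params$tau_ca
    theta_d <- params$theta_d
    theta_p <- params$theta_p
  }
  if (nu < 0) stop("rate must be nonnegative")
  if (C <= 0) stop("amplitude must be positive")
  if (nu == 0) {
    return(structure(list(grid = 0, density = Inf, cdf = 1, Z = 1,
                          point_mass = 1, a_exponent = 0,
                          alpha_d = 0, alpha_p = 0, nu_pre = 0, nu_post = 0,
                          method = "degenerate"), class = "calcium_pdf"))
  }
  a <- nu * tau_ca
  mean_c <- nu * tau_ca * C
  sd_c <- sqrt(nu * tau_ca / 2) * C
  if (is.null(xmax))
    xmax <- max(theta_p / C + 4, (mean_c + 12 * sd_c) / C, 6)
  npan <- ceiling(xmax)
  h <- 1 / m
  # grid over [0, npan] aligned to panel boundaries
  x <- seq(0, npan, by = h)
  Fv <- numeric(length(x))
  p1 <- x <= 1
  Fv[p1] <- x[p1]^a
  # second panel: hypergeometric series term
  S_series <- function(w) {
    # sum_{m>=0} w^(a+1+m)/(a+1+m), |w| < 1
    out <- numeric(length(w))
    term <- w^(a + 1)
    k <- 0
    repeat {
      add <- term / (a + 1 + k)
      out <- out + add
      term <- term * w
      k <- k + 1
      if (all(abs(add) < 1e-16 * pmax(out, 1e-300)) || k > 5000) break
    }
    out
  }
  i2 <- x > 1 & x <= 2
  if (any(i2)) {
    w <- 1 - 1 / x[i2]
    Fv[i2] <- x[i2]^a * (1 - a * S_series(w))
  }
  # panels n >= 2: integrating-factor recursion with trapezoid cumulation
  for (n in seq_len(max(0, npan - 2)) + 1) {
    idx <- which(x > n & x <= n + 1 + 1e-12)
    if (!length(idx)) break
    i_n <- which.min(abs(x - n))
    Fn <- Fv[i_n]
    # integrand g(u) = F(u-1) u^{-a-1} on [n, x]
    useg <- x[c(i_n, idx)]
    g <- Fv[c(i_n, idx) - m] * useg^(-a - 1)
    cumint <- cumsum(c(0, 0.5 * (g[-1] + g[-length(g)]) * diff(useg)))
    Fv[idx] <- useg[-1]^a * (Fn * n^(-a) - a * cumint[-1])
  }
  Z <- Fv[length(Fv)]
  # density p(c) = dF/dc / Z via the flux-balance relation; the first
  # panel is analytic, so lagged arguments below 1 are evaluated exactly
  Fl <- function(xx) {
    out <- numeric(length(xx))
    p1l <- xx > 0 & xx <= 1
    out[p1l] <- xx[p1l]^a
    pos <- xx > 1
    out[pos] <- stats::approx(x, Fv, pmin(xx[pos], npan), rule = 2)$y
    out
  }
  # refine the grid just above each integer panel boundary, where the
  # density drops with unbounded slope (p0 - beta (x - n)^a)
  xr <- as.vector(outer(h * 0.5^(1:45), seq_len(npan - 1), "+"))
  xout <- sort(unique(c(x, xr[xr < npan])))
  Fout <- Fl(xout)
  cdf <- Fout / Z
  grid_c <- xout * C
  dens_x <- ifelse(xout > 0, a / xout * (Fout - Fl(xout - 1)), 0)
  density <- dens_x / (C * Z)
  alpha_of <- function(theta) {
    xt <- theta / C
    if (xt <= 0) return(1)
    if (xt >= npan) return(0)
    # upper-tail mass as a CDF difference (F is exact on the first two
    # panels, so thresholds reachable by one or two jumps are exact)
    (Z - Fl(xt)) / Z
  }
  structure(list(
    grid = grid_c, density = density, cdf = cdf, Z = Z,
    point_mass = 1 / Z,  # mass below the first jump scale (F(C) = 1 raw)
    a_exponent = a, c_min = C,
    alpha_d = alpha_of(theta_d), alpha_p = alpha_of(theta_p),
    nu_pre = nu / 2, nu_post = nu / 2,
    method = "closed_form"), class = "calcium_pdf")
}

#' Fractions of time above the plasticity thresholds
#'
#' Convenience wrapper returning `alpha_d` and `alpha_p`, the long-run
#' fractions of time the calcium trace spends above the depression and
#' potentiation thresholds, computed from the stationary density.
#'
#' @inheritParams ca_stationary_pdf
#' @return Named numeric vector `c(alpha_d, alpha_p)`.
#' @export
alpha_fractions <- function(nu_pre, nu_post, p, hdiv = 400L) {
  pdf <- ca_stationary_pdf(nu_pre, nu_post, p, hdiv = hdiv)
  c(alpha_d = pdf$alpha_d, alpha_p = pdf$alpha_p)
}

#' Monte-Carlo estimate of the threshold time fractions
#'
#' Independent oracle for [alpha_fractions()]: simulates the calcium shot
#' noise event-by-event and accumulates the exact time spent above each
#' threshold, reporting block-based standard errors.
#'
#' @inheritParams ca_stationary_pdf
#' @param n_events number of simulated spike events.
#' @param seed RNG seed.
#' @param n_blocks number of blocks for the standard-error estimate.
#' @return List with `alpha_d`, `alpha_p`, `se_d`, `se_p`.
#' @export
mc_alpha_fractions <- function(nu_pre, nu_post, p, n_events = 1e6,
                               seed = 1, n_blocks = 20L) {
  stopifnot(inherits(p, "plasticity_params"))
  cpp_mc_alpha(nu_pre, nu_post, p$C_pre, p$C_post, p$tau_ca,
               p$theta_d, p$theta_p, n_events, seed, as.integer(n_blocks))
}

#' Minimum number of spikes needed to clear a threshold
#'
#' Smallest number of calcium jumps (any mixture of `C_pre` and `C_post`,
#' arriving simultaneously in the idealisation) whose sum reaches the
#' threshold.  Since the largest available jump can simply be repeated,
#' this is `ceiling(theta / max(C_pre, C_post))`.
#'
#' @param p a [plasticity_params()] object.
#' @param theta positive threshold (defaults to the depression threshold).
#' @return Integer `k >= 1`.
#' @examples
#' min_spikes_to_cross(ca_preset("in_vitro"))  # 1
#' min_spikes_to_cross(ca_preset("in_vivo"))   # 2
#' @export
min_spikes_to_cross <- function(p, theta = p$theta_d) {
  stopifnot(inherits(p, "plasticity_params"))
  if (theta <= 0) stop("theta must be positive")
  cmax <- max(p$C_pre, p$C_post)
  as.integer(ceiling(theta / cmax - 1e-12))
}

#' Low-rate expansions of the threshold time fractions
#'
#' Leading-order expansions of the fraction of time a shot-noise calcium
#' trace with common amplitude `C` spends above a threshold `theta` as the
#' total rate `nu` goes to zero:
#' * one spike suffices (`theta <= C`): `alpha ~ nu tau_ca log(C/theta)`;
#' * two spikes are needed (`C < theta <= 2C`):
#'   `alpha ~ (nu tau_ca)^2 [L log(C/theta) + Li2(-exp(-L)) - Li2(-1)]`
#'   with `L = log(C / (theta - C))` and the dilogarithm `Li2`.
#'
#' @param nu total Poisson rate (spikes/s).
#' @param C common jump amplitude.
#' @param tau_ca calcium decay time (s).
#' @param theta threshold, `0 < theta <= 2C`.
#' @return Expansion value of the time fraction.
#' @export
alpha_low_rate <- function(nu, C, tau_ca, theta) {
  if (theta <= 0) stop("theta must be positive")
  a <- nu * tau_ca
  if (theta <= C) {
    a * log(C / theta)
  } else if (theta <= 2 * C) {
    L <- log(C / (theta - C))
    # dilogarithm by direct series (argument in (-1, 0])
    li2 <- function(z) {
      k <- seq_len(200)
      sum(z^k / k^2)
    }
    li2_m1 <- -pi^2 / 12
    a^2 * (L * log(C / theta) + li2(-exp(-L)) - li2_m1)
  } else {
    stop("expansion implemented for thresholds reachable by one or two spikes")
  }
}

#' Export a stationary calcium density
#'
#' Writes the density as a two-column CSV `(c, density)` and a JSON sidecar
#' with `alpha_d`, `alpha_p`, `Z` and the point mass below the first jump
#' scale.
#'
#' @param pdf a `calcium_pdf` object.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return Invisibly, the two file paths.
#' @export
write_ca_pdf <- function(pdf, path) {
  stopifnot(inherits(pdf, "calcium_pdf"))
  utils::write.csv(data.frame(c = pdf$grid, density = pdf$density),
                   path, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(list(alpha_d = pdf$alpha_d, alpha_p = pdf$alpha_p,
                            Z = pdf$Z, point_mass = pdf$point_mass),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
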