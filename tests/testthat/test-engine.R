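test_that("double-well deterministic update fixes its equilibria", {
  for (r in c(0, 0.5, 1)) {
    for (t in c(0.1, 10, 1e4)) {
      expect_equal(deterministic_update_double_well(r, t, vitro$tau_rho), r)
    }
  }
  tau <- vitro$tau_rho
  eps <- 1e-3
  expect_gt(deterministic_update_double_well(0.5 + eps, tau, tau), 0.5 + eps)
  expect_lt(deterministic_update_double_well(0.5 - eps, tau, tau), 0.5 - eps)
  # flat update is the identity
  expect_identical(deterministic_update_flat(0.37, 100), 0.37)
  expect_error(deterministic_update_flat(0.3, -1), "nonnegative")
  expect_error(deterministic_update_double_well(0.3, 1, tau, rho_star = 0.4),
               "rho_star")
})

test_that("double-well closed form matches a stiff ODE oracle", {
  tau <- vitro$tau_rho
  ode_rho <- function(rho0, t) {
    f <- function(tt, y, parms)
      list(-y * (1 - y) * (0.5 - y) / tau)
    unname(deSolve::ode(y = rho0, times = c(0, t), func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-12, atol = 1e-13)[2, 2])
  }
  # spot value: rho = 0.9 after ten efficacy time constants converges
  # toward 1 at the slow rate 1/(2 tau) -> 0.99905..., not yet 1
  v <- deterministic_update_double_well(0.9, 10 * tau, tau)
  expect_equal(v, ode_rho(0.9, 10 * tau), tolerance = 1e-9)
  expect_gt(v, 0.999)
  expect_lt(v, 1)

  set.seed(5)
  for (i in 1:30) {
    r0 <- runif(1, -0.1, 1.1)
    t <- runif(1, 0, 20) * tau
    expect_lt(abs(deterministic_update_double_well(r0, t, tau) -
                    ode_rho(r0, t)), 1e-9)
  }
})

test_that("OU epoch updates have exact transition moments", {
  # degenerate limits
  expect_equal(stochastic_epoch_update(0.3, 0, 0.7, 10, 0.01), 0.3)
  expect_equal(stochastic_epoch_update(0.3, 1e6, 0.7, 10, 0), 0.7)
  expect_error(stochastic_epoch_update(0.3, -1, 0.7, 10, 0.01),
               "nonnegative")

  rho0 <- 0.9; t <- 0.02
  gsum <- vitro$gamma_p + vitro$gamma_d
  rate <- gsum / vitro$tau_rho
  target <- vitro$gamma_p / gsum
  var_stat <- vitro$sigma^2 / gsum
  x <- stochastic_epoch_update(rho0, t, target, rate, var_stat,
                               n = 1e5, seed = 13)
  e <- exp(-t * rate)
  m_th <- target + (rho0 - target) * e
  v_th <- var_stat * (1 - e^2)
  expect_lt(abs(mean(x) - m_th), 3 * sqrt(v_th / 1e5))
  expect_lt(abs(var(x) - v_th), 3 * v_th * sqrt(2 / (1e5 - 1)))
})

test_that("event-based traces are reproducible and validate inputs", {
  pre <- generate_poisson_train(2, 20, seed = 1)
  post <- generate_poisson_train(2, 20, seed = 2)
  a <- run_synapse(pre, post, vitro, rho0 = 1, duration = 20, seed = 9)
  b <- run_synapse(pre, post, vitro, rho0 = 1, duration = 20, seed = 9)
  expect_identical(a, b)
  d <- run_synapse(pre, post, vitro, rho0 = 1, duration = 20, seed = 10)
  expect_false(identical(a$rho, d$rho))
  expect_error(run_synapse(rev(pre), post, vitro), "sorted")

  # empty trains with the flat potential leave the efficacy untouched
  e <- run_synapse(numeric(0), numeric(0), vitro, rho0 = 0.42,
                   duration = 5, sample_dt = 1)
  expect_true(all(e$rho == 0.42))
})

test_that("no efficacy change without a depression-threshold crossing", {
  # in-vivo amplitudes, sigma = 0: rho moves only when calcium was above
  # theta_d at the start of the inter-event interval
  pre <- generate_poisson_train(1, 120, seed = 3)
  post <- generate_poisson_train(1, 120, seed = 4)
  tr <- run_synapse(pre, post, vivo, rho0 = 0.8, duration = 120,
                    sigma_scale = 0)
  moved <- abs(diff(tr$rho)) > 1e-15
  c_before <- tr$calcium[-nrow(tr)]
  expect_true(all(c_before[moved] > vivo$theta_d))
  # and some subthreshold intervals exist where rho stayed put
  expect_true(any(!moved))
})

test_that("event-based engine matches the fine-step Euler oracle pathwise", {
  pre <- generate_poisson_train(1, 60, seed = 11)
  post <- generate_poisson_train(1, 60, seed = 12)
  for (p in list(vitro, vitro_dw)) {
    ev <- run_synapse(pre, post, p, rho0 = if (p$potential == "flat") 1
                      else 0.8, duration = 60, sample_dt = 0.01,
                      sigma_scale = 0)
    eu <- run_synapse_euler(pre, post, p,
                            rho0 = if (p$potential == "flat") 1 else 0.8,
                            duration = 60, dt_step = 1e-6,
                            sample_dt = 0.01, sigma_scale = 0)
    evs <- stats::approx(ev$time, ev$rho, eu$time, rule = 2)$y
    expect_lt(max(abs(evs - eu$rho)), 1e-3)
  }
})

test_that("stochastic engine and Euler oracle agree in distribution", {
  pre <- generate_poisson_train(2, 20, seed = 21)
  post <- generate_poisson_train(2, 20, seed = 22)
  n <- 400
  ev_final <- vapply(seq_len(n), function(k)
    utils::tail(run_synapse(pre, post, vitro, rho0 = 1, duration = 20,
                            seed = 1000, stream = k)$rho, 1), numeric(1))
  eu_final <- vapply(seq_len(n), function(k)
    utils::tail(run_synapse_euler(pre, post, vitro, rho0 = 1,
                                  duration = 20, dt_step = 1e-4,
                                  seed = 2000, stream = k,
                                  sample_dt = 20)$rho, 1), numeric(1))
  se <- sqrt(var(ev_final) / n + var(eu_final) / n)
  expect_lt(abs(mean(ev_final) - mean(eu_final)), 3 * se)
})

test_that("flat-potential efficacies stay clipped to [0, 1]", {
  pre <- generate_poisson_train(8, 30, seed = 31)
  post <- generate_poisson_train(8, 30, seed = 32)
  tr <- run_synapse(pre, post, vitro, rho0 = 1, duration = 30,
                    sigma_scale = 4)
  expect_true(all(tr$rho >= 0 & tr$rho <= 1))
})

test_that("single-interval advance agrees with the trace engine", {
  st <- list(calcium = 2.0, rho = 0.7, t_last = 0)
  out <- advance_synapse(st, 0.05, vitro, seed = 4, sigma_scale = 0)
  expect_equal(out$calcium, 2.0 * exp(-0.05 / vitro$tau_ca),
               tolerance = 1e-12)
  # flat potential, calcium below threshold: nothing happens
  st2 <- list(calcium = 0.5, rho = 0.7, t_last = 0)
  out2 <- advance_synapse(st2, 1, vitro, seed = 4)
  expect_equal(out2$rho, 0.7)
  expect_error(advance_synapse(st2, -1, vitro), "nonnegative")
})

test_that("ensembles are reproducible and decay toward the OU asymptote", {
  cfg <- experiment_config(1, 1, 300, 200, seed = 5)
  a <- run_ensemble(cfg, vitro)
  b <- run_ensemble(cfg, vitro)
  expect_identical(a, b)
  s <- ou_summary(1, 1, vitro)
  # mean trajectory within 0.02 of theory on [0, 2 tau]
  sel <- a$trace$time <= 2 * s$tau_eff
  th <- mean_trajectory(1, a$trace$time[sel], s)
  expect_lt(max(abs(a$trace$mean_rho[sel] - th)), 0.02 + 3 * 0.1 / sqrt(200))
})
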