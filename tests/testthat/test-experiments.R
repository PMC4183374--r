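test_that("exponential fits recover noiseless parameters exactly", {
  t <- seq(0, 900, by = 5)
  tr <- data.frame(time = t, mean_rho = 0.2 + 0.8 * exp(-t / 150))
  fit <- fit_exponential(tr)
  expect_equal(fit$tau_fit, 150, tolerance = 1e-6)
  expect_equal(fit$asymptote_fit, 0.2, tolerance = 1e-6)
  expect_equal(fit$rho0_fit, 1.0, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("exponential fits tolerate measurement noise", {
  t <- seq(0, 900, by = 5)
  set.seed(8)
  errs <- replicate(50, {
    tr <- data.frame(time = t,
                     mean_rho = 0.2 + 0.8 * exp(-t / 150) +
                       rnorm(length(t), sd = 0.01))
    abs(fit_exponential(tr)$tau_fit / 150 - 1)
  })
  expect_true(all(errs < 0.05))
})

test_that("degenerate traces are rejected", {
  t <- seq(0, 100, by = 5)
  expect_error(fit_exponential(data.frame(time = t, mean_rho = rep(0.3, length(t)))),
               "constant trace")
  expect_error(fit_exponential(data.frame(time = 1:5, mean_rho = exp(-(1:5)))),
               "at least 10")
})

test_that("censored exponential MLE behaves at its edge cases", {
  fp <- data.frame(time = c(2, 4, 6, 10), censored = c(FALSE, FALSE, FALSE, TRUE))
  st <- dwell_time_stats(fp)
  expect_equal(st$mean_dwell, 22 / 3)
  expect_identical(st$n_events, 3L)
  expect_identical(st$n_censored, 1L)
  # all censored: only a lower bound, estimate is infinite
  st2 <- dwell_time_stats(data.frame(time = c(5, 5), censored = c(TRUE, TRUE)))
  expect_identical(st2$mean_dwell, Inf)
  expect_error(dwell_time_stats(data.frame(time = numeric(0),
                                           censored = logical(0))),
               "no crossings")
})

test_that("noiseless bistable synapses below the bifurcation never escape", {
  fp <- simulate_first_passage(20, 1, vivo_dw, rho0 = 1, t_max = 200,
                               seed = 3, sigma_scale = 0)
  expect_true(all(fp$censored))
  expect_identical(dwell_time_stats(fp)$mean_dwell, Inf)
})

test_that("decay experiments are seed-reproducible with theory attached", {
  cfg <- experiment_config(2, 2, 120, 150, seed = 17)
  a <- run_decay_experiment(cfg, vitro)
  b <- run_decay_experiment(cfg, vitro)
  expect_identical(a$trace, b$trace)
  expect_equal(a$fit$tau_fit, b$fit$tau_fit)
  expect_s3_class(a$theory, "ou_summary")
  # fitted decay within 15% of the OU theory at this rate
  expect_lt(abs(a$fit$tau_fit / a$theory$tau_eff - 1), 0.15)
})

test_that("in-vitro bistability leaves decay times unchanged at high rates", {
  nu <- 2
  s <- ou_summary(nu, nu, vitro)
  cfg <- experiment_config(nu, nu, round(5 * s$tau_eff), 800, seed = 33)
  od <- run_decay_experiment(cfg, vitro_dw)
  of <- run_decay_experiment(cfg, vitro)
  expect_lt(abs(od$fit$tau_fit / of$fit$tau_fit - 1), 0.1)
})
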