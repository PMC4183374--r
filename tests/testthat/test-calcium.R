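test_that("calcium decay-and-jump updates are exact", {
  s0 <- list(c = 0, t_last = 0)
  s1 <- ca_decay_jump(s0, 0.5, vitro$C_post, vitro$tau_ca)
  expect_equal(s1$c, 1.23964)

  # a lone in-vitro post spike decays back to theta_d after
  # tau_ca * log(C_post / theta_d) ~ 4.875 ms
  t_cross <- vitro$tau_ca * log(vitro$C_post / vitro$theta_d)
  expect_equal(t_cross, 4.875e-3, tolerance = 2e-3)
  s2 <- ca_decay_jump(s1, 0.5 + t_cross, 0, vitro$tau_ca)
  expect_equal(s2$c, vitro$theta_d, tolerance = 1e-12)

  # a single in-vivo presynaptic transient never reaches theta_d
  s3 <- ca_decay_jump(s0, 1, vivo$C_pre, vivo$tau_ca)
  expect_lt(s3$c, vivo$theta_d)

  expect_error(ca_decay_jump(s1, 0.4, 0, vitro$tau_ca), "ordering")
})

test_that("threshold partition reproduces closed-form crossing times", {
  tc <- vitro$tau_ca
  # below theta_d: case VI, all time below
  pr <- threshold_partition(0.5, 0.1, tc, 1, 1.3)
  expect_equal(pr$t_above_p, 0)
  expect_equal(pr$t_between, 0)
  expect_equal(pr$t_below, 0.1)
  expect_identical(pr$case, "VI")

  # long interval from above theta_p: closed-form crossing times
  c0 <- 2.0
  pr <- threshold_partition(c0, 10, tc, 1, 1.3)
  expect_equal(pr$t_above_p, tc * log(c0 / 1.3), tolerance = 1e-12)
  expect_equal(pr$t_between, tc * log(1.3 / 1), tolerance = 1e-12)
  expect_identical(pr$case, "III")

  expect_error(threshold_partition(1, -0.1, tc, 1, 1.3), "nonnegative")
})

test_that("partition durations match a dense time-grid oracle", {
  set.seed(71)
  tc <- vitro$tau_ca
  for (i in 1:25) {
    c0 <- runif(1, 0, 3)
    dt <- runif(1, 1e-4, 0.2)
    pr <- threshold_partition(c0, dt, tc, 1, 1.3)
    ss <- seq(0, dt, length.out = 1e5 + 1)
    cc <- c0 * exp(-ss / tc)
    w <- dt / 1e5
    above_p <- sum(cc > 1.3) * w
    above_d <- sum(cc > 1) * w
    expect_lt(abs(pr$t_above_p - above_p), 2 * w + 1e-12)
    expect_lt(abs(pr$t_between - (above_d - above_p)), 4 * w + 1e-12)
    expect_lt(abs(pr$t_above_p + pr$t_between + pr$t_below - dt), 1e-12)
  }
})

test_that("crossing case labels follow the sign patterns", {
  tc <- vitro$tau_ca
  expect_identical(threshold_partition(2, 1e-4, tc, 1, 1.3)$case, "I")
  expect_identical(threshold_partition(2, 1.2e-2, tc, 1, 1.3)$case, "II")
  expect_identical(threshold_partition(2, 1, tc, 1, 1.3)$case, "III")
  expect_identical(threshold_partition(1.2, 1e-4, tc, 1, 1.3)$case, "IV")
  expect_identical(threshold_partition(1.2, 1, tc, 1, 1.3)$case, "V")
})

test_that("minimum spike counts to cross thresholds are correct", {
  expect_identical(min_spikes_to_cross(vitro), 1L)
  expect_identical(min_spikes_to_cross(vivo), 2L)
  p3 <- equal_amp_params(1 / 3)
  expect_identical(min_spikes_to_cross(p3), 3L)
  # any parameter set whose largest jump reaches theta needs one spike
  expect_identical(min_spikes_to_cross(vitro, theta = 1.2), 1L)
  expect_identical(min_spikes_to_cross(vivo, theta = 0.7), 1L)
  expect_error(min_spikes_to_cross(vitro, theta = -1), "positive")
})

test_that("degenerate zero-rate density has all mass at zero", {
  pdf <- ca_stationary_pdf(0, 0, vitro)
  expect_equal(pdf$alpha_d, 0)
  expect_equal(pdf$alpha_p, 0)
  expect_equal(pdf$point_mass, 1)
  cf <- ca_stationary_pdf_closed(0, 1, vitro$tau_ca)
  expect_equal(cf$alpha_d, 0)
})

test_that("stationary density normalises and orders the fractions", {
  for (nu in c(0.2, 1, 4)) {
    pdf <- ca_stationary_pdf(nu, nu, vitro)
    mass <- pdf$point_mass + pracma::trapz(pdf$grid, pdf$density)
    expect_lt(abs(mass - 1), 1e-6)
    expect_gte(pdf$alpha_d, pdf$alpha_p)
    expect_gte(pdf$alpha_p, 0)
    expect_lte(pdf$alpha_d, 1)
    # closed-form solver at the matching total rate, equal amplitudes
    cf <- ca_stationary_pdf_closed(2 * nu, 1, vitro$tau_ca)
    above <- cf$grid >= 1
    mass_cf <- cf$point_mass + pracma::trapz(cf$grid[above],
                                             cf$density[above])
    expect_lt(abs(mass_cf - 1), 1e-6)
  }
  expect_error(ca_stationary_pdf(1, 1, vitro, hdiv = 5), "coarse")
})

test_that("closed form and master-equation solver agree for equal amplitudes", {
  pe <- equal_amp_params(1)
  num <- ca_stationary_pdf(1, 1, pe)
  cf <- ca_stationary_pdf_closed(2, 1, pe$tau_ca)
  cg <- seq(0.01, 5, by = 0.01)
  expect_lt(max(abs(ca_pdf_density(num, cg) - ca_pdf_density(cf, cg))),
            1e-4)
  # threshold fractions from the two routes for random rate/amplitude pairs
  set.seed(42)
  for (i in 1:10) {
    nu <- runif(1, 0.5, 6)
    C <- runif(1, 0.5, 1.5)
    pp <- equal_amp_params(C)
    d_cf <- ca_stationary_pdf_closed(2 * nu, C, pp$tau_ca)
    d_num <- ca_stationary_pdf(nu, nu, pp)
    expect_lt(abs(d_cf$alpha_d - d_num$alpha_d), 1e-6)
    expect_lt(abs(d_cf$alpha_p - d_num$alpha_p), 1e-6)
  }
})

test_that("closed form rejects unequal amplitudes", {
  expect_error(ca_stationary_pdf_closed(2, params = vitro),
               "ca_stationary_pdf")
  cf <- ca_stationary_pdf_closed(2, params = equal_amp_params(0.9))
  expect_s3_class(cf, "calcium_pdf")
})

test_that("threshold fractions agree with the Monte-Carlo oracle", {
  set.seed(7)
  draws <- list(c(1, 1), c(0.5, 2), c(3, 1.5), c(2, 2), c(0.8, 0.8))
  for (i in seq_along(draws)) {
    nu <- draws[[i]]
    pdf <- ca_stationary_pdf(nu[1], nu[2], vitro)
    mc <- mc_alpha_fractions(nu[1], nu[2], vitro, n_events = 4e6,
                             seed = 100 + i)
    expect_lt(abs(pdf$alpha_d - mc$alpha_d), 3 * mc$se_d)
    expect_lt(abs(pdf$alpha_p - mc$alpha_p), 3 * mc$se_p)
  }
})

test_that("threshold fractions increase with the firing rate", {
  for (p in list(vitro, vivo)) {
    nus <- c(0.25, 0.5, 1, 2, 4, 8)
    ad <- vapply(nus, function(nu) ca_stationary_pdf(nu, nu, p)$alpha_d,
                 numeric(1))
    ap <- vapply(nus, function(nu) ca_stationary_pdf(nu, nu, p)$alpha_p,
                 numeric(1))
    expect_true(all(diff(ad) > 0))
    expect_true(all(diff(ap) > 0))
  }
})

test_that("low-rate expansions match the exact fractions to leading order", {
  # one-spike threshold: alpha_d for the postsynaptic amplitude alone
  r1 <- vapply(c(0.3, 0.1, 0.03, 0.01), function(nu) {
    ex <- ca_stationary_pdf_closed(nu, 1.23964, vitro$tau_ca,
                                   theta_d = 1)$alpha_d
    alpha_low_rate(nu, 1.23964, vitro$tau_ca, 1) / ex
  }, numeric(1))
  expect_true(all(abs(r1 - 1) < 0.1))
  expect_lt(abs(r1[length(r1)] - 1), 0.01)

  # two-spike threshold: dilogarithm expansion of alpha_p, two decades
  r2 <- vapply(c(1, 0.3, 0.1, 0.03, 0.01), function(nu) {
    ex <- ca_stationary_pdf_closed(nu, 1, vitro$tau_ca)$alpha_p
    alpha_low_rate(nu, 1, vitro$tau_ca, 1.3) / ex
  }, numeric(1))
  expect_true(all(abs(r2 - 1) < 0.05))
  expect_lt(abs(r2[length(r2)] - 1), 0.005)

  expect_error(alpha_low_rate(1, 0.3, vitro$tau_ca, 1), "two spikes")
})

test_that("density export writes CSV plus JSON sidecar", {
  pdf <- ca_stationary_pdf(1, 1, vivo)
  f <- tempfile(fileext = ".csv")
  paths <- write_ca_pdf(pdf, f)
  expect_true(all(file.exists(paths)))
  d <- utils::read.csv(f)
  expect_identical(names(d), c("c", "density"))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$alpha_d, pdf$alpha_d, tolerance = 1e-12)
  expect_equal(side$point_mass, pdf$point_mass, tolerance = 1e-12)
  unlink(paths)
})
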