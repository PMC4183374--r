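test_that("silent synapses feel the bare double well", {
  L <- effective_potential(0, vivo_dw)
  expect_equal(L$fixed_points, c(0, 0.5, 1), tolerance = 1e-6)
  expect_equal(L$sigma_eff, 0)
  # and the flat potential is rejected
  expect_error(effective_potential(1, vivo), "double-well")
})

test_that("in-vivo landscape is bistable below and monostable above nu_c", {
  expect_length(effective_potential(0.1, vivo_dw)$fixed_points, 3)
  expect_length(effective_potential(1, vivo_dw)$fixed_points, 3)
  expect_length(effective_potential(2, vivo_dw)$fixed_points, 1)
})

test_that("saddle-node bifurcation rates match their regression values", {
  nu_c <- bifurcation_rate(vivo_dw)
  expect_equal(nu_c, 1.31, tolerance = 0.01)
  # the larger in-vitro calcium amplitudes destroy bistability much earlier
  nu_c_vitro <- bifurcation_rate(vitro_dw, lower = 2e-3)
  expect_equal(nu_c_vitro, 0.0383, tolerance = 0.05)
  expect_lt(nu_c_vitro, nu_c)
  expect_error(bifurcation_rate(vivo_dw, lower = 3), "lower bracket")
})

test_that("fixed points are independent of the noise amplitude", {
  a <- effective_potential(1, vivo_dw, sigma_scale = 1)
  b <- effective_potential(1, vivo_dw, sigma_scale = 2)
  expect_equal(a$fixed_points, b$fixed_points, tolerance = 1e-10)
  expect_equal(b$sigma_eff, 2 * a$sigma_eff, tolerance = 1e-12)
})

test_that("escape times shrink with rate and explode with barrier height", {
  nus <- c(0.4, 0.6, 0.8, 1, 1.2)
  Ts <- vapply(nus, function(nu) kramers_escape_time(nu, vivo_dw),
               numeric(1))
  expect_true(all(diff(Ts) < 0))
  # near the bifurcation the barrier vanishes and T collapses toward the
  # intrawell relaxation scale (orders of magnitude below T at 1/s)
  expect_lt(Ts[length(Ts)] / Ts[4], 0.05)
  expect_error(kramers_escape_time(2, vivo_dw), "monostable")
})

test_that("UP-state minimum recedes continuously from 1 as rate grows", {
  nus <- seq(0.1, 1.25, length.out = 6)
  ups <- vapply(nus, function(nu) {
    fp <- effective_potential(nu, vivo_dw)$fixed_points
    fp[length(fp)]
  }, numeric(1))
  expect_true(all(diff(ups) < 0))
  expect_lt(1 - ups[1], 0.01)
})

test_that("monostable minimum approaches the OU asymptote at high rates", {
  for (nu in c(8, 12)) {
    L <- effective_potential(nu, vivo_dw)
    s <- ou_summary(nu, nu, vivo_dw)
    expect_length(L$fixed_points, 1)
    expect_equal(L$fixed_points[1], s$rho_bar_unbounded, tolerance = 0.05)
  }
})

test_that("flat and double-well relaxation times merge at high rates", {
  nu_c <- 1.31
  for (m in c(3, 4)) {
    nu <- m * nu_c
    L <- effective_potential(nu, vivo_dw)
    tau_dw <- vivo_dw$tau_rho / L$d2U_eff(L$fixed_points[1])
    tau_flat <- decay_time_constant(nu, nu, vivo)
    expect_lt(abs(tau_dw / tau_flat - 1), 0.1)
  }
})

test_that("stationary efficacy distribution matches the regime", {
  # flat potential: truncated Gaussian centred near the OU asymptote
  d <- stationary_efficacy_dist(1, vitro)
  m <- pracma::trapz(d$grid, d$grid * d$pdf)
  expect_equal(m, asymptotic_mean(1, 1, vitro), tolerance = 0.01)
  # double well at 1/s in vivo: depression dominates, so the equilibrium
  # measure concentrates in the DOWN well (the UP state is metastable)
  d2 <- stationary_efficacy_dist(1, vivo_dw)
  up_mass <- pracma::trapz(d2$grid[d2$grid > 0.5],
                           d2$pdf[d2$grid > 0.5])
  expect_lt(up_mass, 1e-4)
  # reverse-lookup sampling is reproducible and respects the distribution
  r1 <- sample_stationary_rho(500, 1, vivo_dw, seed = 9)
  r2 <- sample_stationary_rho(500, 1, vivo_dw, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0 & r1 <= 1))
  expect_gt(mean(r1 < 0.1), 0.95)
})
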