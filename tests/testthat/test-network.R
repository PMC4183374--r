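net_small <- network_params(N_E = 200L, N_I = 50L)

test_that("random connectivity excludes autapses and hits its density", {
  adj <- build_adjacency(net_small, seed = 2)
  expect_false(any(adj$src == adj$dst))
  N <- net_small$N_E + net_small$N_I
  n_exp <- net_small$p_conn * N * (N - 1)
  expect_lt(abs(length(adj$src) - n_exp), 4 * sqrt(n_exp))
  # E-to-E edges carry consecutive plastic ids, others -1
  is_ee <- adj$src < net_small$N_E & adj$dst < net_small$N_E
  expect_identical(sort(adj$syn[is_ee]), seq_len(adj$n_syn) - 1L)
  expect_true(all(adj$syn[!is_ee] == -1L))
  expect_identical(build_adjacency(net_small, seed = 2), adj)
})

test_that("network simulations are bit-reproducible for a fixed seed", {
  a <- simulate_network(net_small, vitro, 3, seed = 5, rho_init = 0.2)
  b <- simulate_network(net_small, vitro, 3, seed = 5, rho_init = 0.2)
  expect_identical(a$raster, b$raster)
  expect_identical(a$rho_final, b$rho_final)
  c2 <- simulate_network(net_small, vitro, 3, seed = 6, rho_init = 0.2)
  expect_false(identical(a$raster, c2$raster))
})

test_that("disconnected LIF rates match the Siegert transfer function", {
  net <- network_params()
  pred <- siegert_rate(net$mu_ext, net$sigma_ext, net$tau_m, net$V_th,
                       net$V_r, net$V_L)
  ras <- simulate_lif_neurons(150, 150, net, seed = 3)
  sim <- nrow(ras) / (150 * 150)
  expect_lt(abs(sim / pred - 1), 0.05)
})

test_that("ISI statistics flag Poisson and reset-potential signatures", {
  # Poisson surrogate: CV near 1 and short-ISI mass at its exponential
  # reference
  ras <- do.call(rbind, lapply(1:30, function(k)
    data.frame(time = generate_poisson_train(2, 400, seed = 100 + k),
               neuron = k)))
  s <- isi_statistics(ras)
  expect_lt(abs(s$cv - 1), 0.05)
  expect_lt(abs(s$ratio - 1), 0.1)
  ks <- suppressWarnings(stats::ks.test(s$isi, "pexp", 1 / mean(s$isi)))
  expect_gt(ks$p.value, 0.01)

  expect_error(isi_statistics(ras[1:20, ]), "too few")

  # depolarised reset (-55 mV) over-represents short ISIs, hyperpolarised
  # (-70 mV) under-represents them, relative to Poisson
  net <- network_params()
  ratios <- vapply(c(-55, -60, -70), function(vr) {
    r <- simulate_lif_neurons(60, 250, net, V_r = vr, seed = 4)
    isi_statistics(r)$ratio
  }, numeric(1))
  expect_gt(ratios[1], 1)
  expect_lt(ratios[3], 1)
  expect_true(all(diff(ratios) < 0))
})

test_that("short-ISI excess raises the realised synaptic efficacy", {
  net <- network_params()
  mean_rho <- vapply(c(-55, -60, -70), function(vr) {
    ras <- simulate_lif_neurons(40, 400, net, V_r = vr, seed = 7)
    trains <- split(ras$time, ras$neuron)
    # pair consecutive neurons into pre/post of tracked synapses
    rho_fin <- vapply(seq_len(20), function(k) {
      utils::tail(run_synapse(trains[[2 * k - 1]], trains[[2 * k]], vitro,
                              rho0 = 0.5, duration = 400, seed = 50,
                              stream = k)$rho, 1)
    }, numeric(1))
    mean(rho_fin)
  }, numeric(1))
  # monotone association across the three reset settings
  expect_true(all(diff(mean_rho) < 0))
})

test_that("memory implant initialises and tags as configured", {
  run <- simulate_network(net_small, vitro, 2, seed = 11, rho_init = 0.2,
                          tag_fraction = 0.05, record_raster = FALSE)
  expect_equal(mean(run$tagged), 0.05, tolerance = 0.01)
  expect_true(all(run$rho_init[run$tagged] == 1))
  expect_true(all(run$rho_init[!run$tagged] == 0.2))
  expect_equal(run$rho_traces$tagged[1], 1)
})

test_that("stationary-CDF initialisation matches the predicted wells", {
  run <- simulate_network(net_small, vivo_dw, 1, seed = 12,
                          rho_init = "stationary_cdf", stationary_rate = 1,
                          record_raster = FALSE)
  # in-vivo double well at 1/s: equilibrium mass sits in the DOWN well
  expect_gt(mean(run$rho_init < 0.1), 0.95)
  run2 <- simulate_network(net_small, vitro, 1, seed = 12,
                           rho_init = "stationary_cdf",
                           stationary_rate = 1, record_raster = FALSE)
  expect_equal(mean(run2$rho_init), asymptotic_mean(1, 1, vitro),
               tolerance = 0.03)
})
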