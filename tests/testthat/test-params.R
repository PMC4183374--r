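test_that("published presets carry the expected constants", {
  expect_equal(vitro$C_pre, 0.56175)
  expect_equal(vitro$C_post, 1.23964)
  expect_equal(vitro$tau_ca, 22.6936e-3)
  expect_equal(vitro$theta_d, 1)
  expect_equal(vitro$theta_p, 1.3)
  expect_equal(vitro$gamma_d, 331.909)
  expect_equal(vitro$gamma_p, 725.085)
  expect_equal(vitro$sigma, 3.3501)
  expect_equal(vitro$tau_rho, 346.3615)
  expect_equal(vitro$rho_star, 0.5)
  expect_equal(vitro$D, 4.6098e-3)

  expect_equal(vivo$C_pre, 0.33705)
  expect_equal(vivo$C_post, 0.74378)
  shared <- setdiff(names(unclass(vitro)), c("C_pre", "C_post"))
  expect_identical(unclass(vitro)[shared], unclass(vivo)[shared])

  # amplitude ratio equals the extracellular calcium ratio 1.5/2.5
  expect_equal(vivo$C_pre / vitro$C_pre, 0.6, tolerance = 1e-9)
})

test_that("preset internal-consistency checks hold", {
  # a lone postsynaptic spike crosses the depression threshold in vitro
  expect_gt(vitro$C_post, vitro$theta_d)
  # ... but not in vivo
  expect_lt(vivo$C_post, vivo$theta_d)
  # potentiation rate dominates depression
  expect_gt(vitro$gamma_p, vitro$gamma_d)
  expect_gt(vitro$theta_p, vitro$theta_d)
})

test_that("unknown presets and invalid parameters are rejected", {
  expect_error(ca_preset("in_silico"), "unknown preset")
  expect_error(plasticity_params(0.5, 1.2, 0.02, theta_d = 1.3,
                                 theta_p = 1, gamma_d = 300, gamma_p = 700,
                                 sigma = 3, tau_rho = 300),
               "theta_p > theta_d")
  expect_error(plasticity_params(0.5, 1.2, 0.02, 1, 1.3, gamma_d = 700,
                                 gamma_p = 300, sigma = 3, tau_rho = 300),
               "gamma_p > gamma_d")
  expect_error(plasticity_params(-0.5, 1.2, 0.02, 1, 1.3, 300, 700, 3, 300),
               "positive")
  expect_error(plasticity_params(0.5, 1.2, 0.02, 1, 1.3, 300, 700, 3, 300,
                                 rho_star = 0.4,
                                 potential = "double_well"),
               "rho_star = 0.5")
})

test_that("calcium scaling reproduces the in-vivo amplitudes", {
  scaled <- scale_calcium(vitro, 0.6)
  expect_equal(round(scaled$C_pre, 5), vivo$C_pre)
  expect_equal(round(scaled$C_post, 5), vivo$C_post)  # 0.6*1.23964 = 0.743784
  shared <- setdiff(names(unclass(vitro)), c("C_pre", "C_post"))
  expect_identical(unclass(scaled)[shared], unclass(vitro)[shared])

  expect_identical(scale_calcium(vitro, 1), vitro)
  expect_error(scale_calcium(vitro, 0), "positive")
  expect_error(scale_calcium(vitro, -2), "positive")
})

test_that("scaling round-trips to machine precision", {
  for (r in c(0.3, 0.6, 1.7, 3.14)) {
    back <- scale_calcium(scale_calcium(vitro, r), 1 / r)
    expect_equal(back$C_pre, vitro$C_pre, tolerance = 1e-14)
    expect_equal(back$C_post, vitro$C_post, tolerance = 1e-14)
  }
})

test_that("experiment configurations are validated", {
  expect_error(experiment_config(-1, 1, 10), "nonnegative")
  expect_error(experiment_config(1, 1, 0), "positive")
  expect_error(experiment_config(1, 1, 10, n_synapses = 0), "at least 1")
  cfg <- experiment_config(1, 2, 10, 5, seed = 3, rho_init = 0.5)
  expect_s3_class(cfg, "experiment_config")
  expect_identical(cfg$n_synapses, 5L)
})
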