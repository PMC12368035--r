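# composed experiments: activation-curve shift, pulse decay, rate scans

test_that("with no pumps the pipette experiment reproduces the pure curve", {
  cv <- run_steady_experiment(default_geom(), pump_params(0),
                              truth$bk_steady, c_pip = 10,
                              n_r = 24, n_theta = 48)
  ref <- steady_activation_curve(truth$bk_steady, 10, cv$voltages)
  expect_lt(max(abs(cv$g_norm - ref$g_norm)), 1e-6)
  expect_equal(cv$fitted_vh, ref$fitted_vh, tolerance = 1e-4)
})

test_that("faster pumps shift activation to more positive potentials", {
  g <- default_geom()
  vh <- vapply(c(50, 5000, 1e6), function(phi) {
    run_steady_experiment(g, pump_params(phi), truth$bk_steady,
                          n_r = 24, n_theta = 48)$fitted_vh
  }, numeric(1))
  expect_true(all(diff(vh) > 0))
  # extreme rates pin the membrane at rest: curve approaches the
  # resting-calcium calibration
  ref <- steady_activation_curve(truth$bk_steady, 0.1,
                                 seq(-80, 240, by = 10))
  expect_lt(abs(vh[3] - ref$fitted_vh), 2)
})

test_that("pulse decay with strong buffering is deactivation-limited", {
  tr <- run_pulse_experiment(default_geom(), pump_params(0),
                             buffer_params(1e4), short_protocol(),
                             truth$bk_kinetic, influx = "step",
                             n_shells = 20)
  expect_false(tr$fit$failed)
  tau_deact <- gating_relaxation_tau(70, 0.1, truth$bk_kinetic)
  expect_equal(tr$tau_decay, tau_deact, tolerance = 0.12)
})

test_that("weak buffering without pumps leaves a persistent response", {
  tr <- run_pulse_experiment(default_geom(), pump_params(0),
                             buffer_params(0), short_protocol(record = 120),
                             truth$bk_kinetic, n_shells = 20)
  expect_true(tr$persistent || (!tr$fit$failed && tr$tau_decay > 50))
})

test_that("pump flux enters only as cycle rate times density", {
  g <- default_geom()
  pr <- short_protocol(record = 50)
  t1 <- run_pulse_experiment(g, pump_params(10000, density = 50),
                             buffer_params(0), pr, truth$bk_kinetic,
                             n_shells = 20)
  t2 <- run_pulse_experiment(g, pump_params(5000, density = 100),
                             buffer_params(0), pr, truth$bk_kinetic,
                             n_shells = 20)
  expect_equal(t1$tau_decay, t2$tau_decay, tolerance = 1e-6)
})

test_that("repeated influx pulses prolong the decay in both clearance modes", {
  g <- default_geom()
  tau1 <- run_pulse_experiment(g, pump_params(20000), buffer_params(0),
                               short_protocol(1), truth$bk_kinetic,
                               n_shells = 20)$tau_decay
  tau5 <- run_pulse_experiment(g, pump_params(20000), buffer_params(0),
                               short_protocol(5), truth$bk_kinetic,
                               n_shells = 20)$tau_decay
  expect_gte(tau5, tau1)
  # buffer condition: only the sub-membrane calcium activates the channels
  taub1 <- run_pulse_experiment(g, pump_params(0), buffer_params(1e4),
                                short_protocol(1), truth$bk_kinetic,
                                readout = "membrane",
                                n_shells = 20)$tau_decay
  taub5 <- run_pulse_experiment(g, pump_params(0), buffer_params(1e4),
                                short_protocol(5), truth$bk_kinetic,
                                readout = "membrane",
                                n_shells = 20)$tau_decay
  expect_gte(taub5, taub1)
})

test_that("steady-mode rate scan reports monotone shifts and a threshold", {
  sc <- scan_pump_rates(c(50, 5000), mode = "steady",
                        geometry = default_geom(), pump = pump_params(),
                        bk_steady = truth$bk_steady,
                        n_r = 24, n_theta = 48)
  expect_equal(nrow(sc$table), 2)
  expect_lt(sc$table$vh_mV[1], sc$table$vh_mV[2])
  expect_true(is.finite(sc$reference))
  expect_true(sc$table$within_overlay[2])
  expect_equal(sc$minimal_sufficient_rate, 5000)
  expect_error(scan_pump_rates(50, mode = "steady",
                               geometry = default_geom(),
                               pump = pump_params(),
                               bk_steady = truth$bk_steady), "2 rates")
})
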