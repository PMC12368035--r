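# synthetic data generation and end-to-end pipeline self-consistency

test_that("truth set satisfies its behavioural anchors", {
  tau <- gating_relaxation_tau(70, 0.1, truth$bk_kinetic)
  expect_gte(tau, 7)
  expect_lte(tau, 9)
  vg <- seq(-80, 240, by = 10)
  vh <- vapply(c(0.1, 1, 10, 50), function(cc)
    steady_activation_curve(truth$bk_steady, cc, vg)$fitted_vh, numeric(1))
  expect_true(all(diff(vh) < 0))
  expect_gt(vh[1] - vh[3], 0)
  # the kinetic set embeds exactly its steady set
  eq <- gating_equilibrium(100, 5, truth$bk_kinetic)
  expect_equal(sum(eq[6:10]), popen_steady(100, 5, truth$bk_steady),
               tolerance = 1e-8)
})

test_that("generation is seed-deterministic and clipped", {
  a <- gen_activation_curves(truth, noise_sigma = 0.05, seed = 3)
  b <- gen_activation_curves(truth, noise_sigma = 0.05, seed = 3)
  expect_identical(a, b)
  expect_true(all(a$g_norm >= 0 & a$g_norm <= 1.05))
  c0 <- gen_activation_curves(truth, noise_sigma = 0, seed = 1)
  c1 <- gen_activation_curves(truth, noise_sigma = 0, seed = 99)
  expect_equal(c0$g_norm, c1$g_norm, tolerance = 1e-12)  # noiseless = model
  r1 <- gen_replica_counts(55, rep(2, 8), seed = 5)
  r2 <- gen_replica_counts(55, rep(2, 8), seed = 5)
  expect_identical(r1, r2)
  expect_true(all(gen_replica_counts(0, rep(2, 8), seed = 1)$count == 0))
})

test_that("switch generator respects trivial orderings", {
  flat <- gen_switch_responses(truth, c_from = 1, c_to = 1, v_hold = 70,
                               duration = 10, dt = 0.1)[[1]]
  expect_lt(diff(range(flat$values)), 1e-8)
  up <- gen_switch_responses(truth, c_from = 0.1, c_to = 10, v_hold = 70,
                             duration = 30, dt = 0.1)[[1]]
  expect_gt(up$values[length(up$values)], up$values[1])
  expect_equal(up$values[length(up$values)],
               popen_steady(70, 10, truth$bk_steady), tolerance = 1e-3)
})

test_that("pooled synthetic replica density matches the truth within 3 SE", {
  tab <- gen_replica_counts(55, areas = rep(10, 10), seed = 2)
  pooled <- sum(tab$count) / sum(tab$area_um2)
  se <- sqrt(55 / sum(tab$area_um2))
  expect_lt(abs(pooled - 55), 3 * se)
})

test_that("dataset writer emits readable files and a manifest", {
  dir <- withr::local_tempdir()
  man <- write_synthetic_dataset(dir, truth, seed = 1)
  expect_true(all(file.exists(file.path(dir, man$files))))
  curves <- utils::read.delim(file.path(dir, "activation_curves.tsv"))
  expect_identical(names(curves), c("c_uM", "voltage_mV", "g_norm"))
  regen <- gen_activation_curves(truth, noise_sigma = man$noise_sigma,
                                 seed = man$seed)
  expect_equal(curves$g_norm, regen$g_norm, tolerance = 1e-12)
})

test_that("calibrating on generated data reproduces the pulse readout", {
  # end-to-end self-consistency: fit the gating model to synthetic
  # calibration data, rerun the pulse experiment with the fitted set, and
  # compare the decay constant against the truth-parameter run
  curves <- gen_activation_curves(truth, noise_sigma = 0, seed = 1)
  st <- calibrate_steady(curves, n_starts = 16, seed = 1)
  sw <- gen_switch_responses(truth, c_from = c(0.1, 10), c_to = c(10, 0.1),
                             v_hold = 70, duration = 60, dt = 0.1)
  kin <- calibrate_kinetic(sw, st$params, n_starts = 8, seed = 1)
  # compare on the buffer-limited validation condition, whose decay is
  # governed by the deactivation kinetics the calibration demonstrably pins
  g <- default_geom()
  pr <- short_protocol(record = 50)
  tau_truth <- run_pulse_experiment(g, pump_params(0), buffer_params(1e4),
                                    pr, truth$bk_kinetic, influx = "step",
                                    n_shells = 20)$tau_decay
  tau_fit <- run_pulse_experiment(g, pump_params(0), buffer_params(1e4),
                                  pr, kin$params, influx = "step",
                                  n_shells = 20)$tau_decay
  expect_lt(abs(tau_fit - tau_truth) / tau_truth, 0.10)
})
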