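# ten-state gating model: closed-form steady state, generator, propagation

toy_steady <- function() {
  bk_steady_params(l0 = 9, gating_charge_q = 1.2,
                   kc = c(10, 10, 10, 10), ko = c(1, 1, 1, 1))
}

test_that("B(c) equals the ratio of the binding polynomials", {
  p <- toy_steady()
  expect_equal(b_factor(0, p), 1, tolerance = 1e-12)
  # large-c limit: prod(ko)/prod(kc)
  expect_equal(b_factor(1e7, p), prod(p$ko) / prod(p$kc), tolerance = 1e-3)
  # direct polynomial evaluation at c = 1 uM for the toy constants
  pc <- 1 + 1 / 10 + 1 / 100 + 1 / 1000 + 1 / 10000
  po <- 1 + 1 + 1 + 1 + 1
  expect_equal(b_factor(1, p), pc / po, tolerance = 1e-12)
  expect_error(b_factor(-1, p), ">= 0")
})

test_that("steady open probability has the Boltzmann structure", {
  p <- truth$bk_steady
  const <- physical_constants()
  # half activation where B * L0 * exp(-QFV/RT) = 1
  vh <- log(p$l0 * b_factor(1, p)) /
    (p$gating_charge_q * const$faraday_over_RT_mV)
  expect_equal(popen_steady(vh, 1, p), 0.5, tolerance = 1e-10)
  expect_equal(popen_steady(1e4, 1, p), 1, tolerance = 1e-6)
  expect_equal(popen_steady(0, 0, toy_steady()), 0.1, tolerance = 1e-12)
  # strictly increasing in V and in c
  expect_true(all(diff(popen_steady(seq(-100, 250, 10), 1, p)) > 0))
  expect_true(all(diff(popen_steady(70, c(0.1, 1, 10, 50), p)) > 0))
})

test_that("activation curves are normalized and shift with calcium", {
  p <- truth$bk_steady
  vg <- seq(-80, 240, by = 10)
  cv <- steady_activation_curve(p, 10, vg)
  expect_equal(max(cv$g_norm), 1)
  expect_true(all(diff(cv$g_norm) >= 0))
  vh <- vapply(c(0.1, 1, 10, 50), function(cc)
    steady_activation_curve(p, cc, vg)$fitted_vh, numeric(1))
  expect_true(all(diff(vh) < 0))
})

test_that("generator rows sum to zero and binding stops at zero calcium", {
  p <- truth$bk_kinetic
  set.seed(42)
  for (i in 1:10) {
    G <- build_generator(runif(1, -80, 200), runif(1, 0, 50), p)
    expect_lt(max(abs(rowSums(G))), 1e-7 * max(abs(G)))
  }
  G0 <- build_generator(70, 0, p)
  bind_idx <- cbind(c(1:4, 6:9), c(2:5, 7:10))
  expect_true(all(G0[bind_idx] == 0))
})

test_that("detailed balance holds around every binding/gating loop", {
  p <- truth$bk_kinetic
  for (vc in list(c(0, 1), c(70, 0.1), c(150, 10), c(-60, 25))) {
    G <- build_generator(vc[1], vc[2], p)
    expect_lt(max(abs(loop_imbalance(G))), 1e-8)
  }
})

test_that("generator equilibrium reproduces the closed-form open probability", {
  p <- truth$bk_kinetic
  set.seed(7)
  for (i in 1:20) {
    v <- runif(1, -80, 220); cc <- runif(1, 0.01, 60)
    eq <- gating_equilibrium(v, cc, p)
    expect_equal(sum(eq[6:10]), popen_steady(v, cc, p$steady),
                 tolerance = 1e-6)
  }
})

test_that("master-equation propagation is consistent with the steady state", {
  p <- truth$bk_kinetic
  tt <- seq(0, 150, by = 0.05)
  # constant conditions converge to the closed-form steady value
  tr <- popen_dynamic(tt, rep(3, length(tt)), rep(70, length(tt)), p,
                      init = gating_equilibrium(70, 0.1, p))
  expect_lt(abs(tr$values[length(tr$values)] -
                  popen_steady(70, 3, p$steady)), 1e-4)
  # starting at equilibrium the trace is flat
  tr0 <- popen_dynamic(tt, rep(3, length(tt)), rep(70, length(tt)), p,
                       init = gating_equilibrium(70, 3, p))
  expect_lt(diff(range(tr0$values)), 1e-6)
})

test_that("deactivation after a calcium drop matches the generator eigenvalue", {
  p <- truth$bk_kinetic
  tau_eig <- gating_relaxation_tau(70, 0.1, p)
  sw <- gen_switch_responses(truth, c_from = 10, c_to = 0.1, v_hold = 70,
                             duration = 80, dt = 0.02)[[1]]
  ft <- fit_monoexponential(sw$times, sw$values)
  expect_false(ft$failed)
  expect_equal(ft$tau, tau_eig, tolerance = 0.06)
})

test_that("surface averaging of open probability is an area-weighted mean", {
  p <- truth$bk_steady
  uniform <- list(membrane_ca = rep(3, 5), membrane_weights = rep(2, 5))
  expect_equal(popen_surface_average(uniform, 70, p),
               popen_steady(70, 3, p), tolerance = 1e-12)
  # two equally weighted nodes average their local open probabilities
  po <- popen_steady(70, c(1, 10), p)
  two <- list(membrane_ca = c(1, 10), membrane_weights = c(1, 1))
  expect_equal(popen_surface_average(two, 70, p), mean(po),
               tolerance = 1e-12)
  expect_error(popen_surface_average(list(membrane_ca = numeric(0),
                                          membrane_weights = numeric(0)),
                                     70, p), "membrane")
  # gradient field: average bounded by the extreme local values
  f <- solve_stationary(default_geom(), pump_params(5000), 10,
                       n_r = 24, n_theta = 48)
  pa <- popen_surface_average(f, 150, p)
  expect_gte(pa, popen_steady(150, min(f$membrane_ca), p))
  expect_lte(pa, popen_steady(150, max(f$membrane_ca), p))
})

test_that("kinetic parameterization rejects malformed inputs", {
  expect_error(bk_kinetic_params(truth$bk_steady, rep(1, 4)), "5")
  expect_error(bk_kinetic_params(truth$bk_steady, rep(1, 5),
                                 charge_split = 1.5), "charge_split")
  expect_error(bk_steady_params(-1, 1.2, rep(1, 4), rep(1, 4)), "positive")
})
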