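# dynamic reaction-diffusion solver and its well-mixed oracle

test_that("equilibrium initial state stays at rest", {
  g <- default_geom()
  pr <- influx_protocol(ions_per_pulse = 1e-9, record_duration = 10)
  # pump + leak active, buffer present, essentially no influx
  ts <- solve_dynamic(g, pump_params(5000), buffer_params(100), pr)
  expect_lt(max(abs(ts$summary$c_volume_uM - 0.1)), 1e-6)
  expect_lt(max(abs(ts$summary$c_membrane_uM - 0.1)), 1e-6)
})

test_that("closed system conserves total calcium to 1e-6 relative", {
  g <- default_geom()
  pr <- influx_protocol(record_duration = 20)
  ts <- solve_dynamic(g, pump_params(0), buffer_params(100), pr)
  ions <- total_calcium_ions(ts)
  after <- ions[ts$times >= 0.8]           # influx over, system closed
  expect_lt(diff(range(after)) / after[1], 1e-6)
  # and the influx itself added exactly the prescribed ions
  expect_equal(after[length(after)] - ions[1], 1.2e6, tolerance = 1e-4)
})

test_that("well-mixed oracle: saturated pump removal rate and buffer equilibrium", {
  g <- default_geom()
  const <- physical_constants()
  # peak concentration removal rate at pump saturation
  p <- pump_params(20000, 50)
  rate_uM_per_ms <- p$cycle_rate * p$density * g$surface_area /
    (g$accessible_volume * const$ions_per_uM_um3) / 1000
  expect_equal(rate_uM_per_ms, 3.40, tolerance = 2e-3)
  # free buffer fraction at rest
  b <- buffer_params(100, k_on = 2.7, k_off = 0.4)
  expect_equal(b$k_off / (b$k_off + b$k_on * 0.1), 0.597, tolerance = 1e-3)
  # the oracle itself holds its steady state
  pr <- influx_protocol(ions_per_pulse = 1e-9, record_duration = 5)
  wm <- wellmixed_reference(g, pump_params(5000), b, pr)
  expect_lt(max(abs(wm$c_uM - 0.1)), 1e-8)
})

test_that("spatial solver matches the well-mixed oracle when diffusion is fast", {
  g <- default_geom()
  pr <- influx_protocol(record_duration = 80)
  p <- pump_params(2000)
  b_fast <- buffer_params(100, diff_coeff = 110 * 100)
  ts <- solve_dynamic(g, p, b_fast, pr, d_ca = 220 * 100, n_shells = 20)
  wm <- wellmixed_reference(g, p, b_fast, pr, times = ts$times)
  # compare concentrations over the transient; near the resting floor the
  # steep clearance makes pointwise relative differences a measure of tiny
  # time shifts, so the clearance time is compared there instead
  sel <- wm$c_uM > 0.5 & ts$times > 1   # clearance phase, above the floor
  rel <- abs(ts$summary$c_volume_uM[sel] - wm$c_uM[sel]) / wm$c_uM[sel]
  expect_lt(max(rel), 0.02)
  t_pde <- crossing_time(ts$times, ts$summary$c_volume_uM, 0.5)
  t_ode <- crossing_time(wm$time_ms, wm$c_uM, 0.5)
  expect_lt(abs(t_pde - t_ode) / t_ode, 0.02)
})

test_that("10 mM chelator absorbs the influx within a millisecond of pulse end", {
  g <- default_geom()
  pr <- influx_protocol(record_duration = 10)
  ts <- solve_dynamic(g, pump_params(0), buffer_params(1e4), pr)
  c_at <- function(t) ts$summary$c_volume_uM[which.min(abs(ts$times - t))]
  expect_lt(c_at(1.8), 1)
  expect_lt(c_at(3), 0.2)
})

test_that("refining the radial mesh leaves decay summaries within 2%", {
  g <- default_geom()
  pr <- influx_protocol(record_duration = 30)
  ts1 <- solve_dynamic(g, pump_params(20000), buffer_params(0), pr,
                       n_shells = 20)
  ts2 <- solve_dynamic(g, pump_params(20000), buffer_params(0), pr,
                       n_shells = 40)
  # volume-averaged concentration at pulse end
  cv1 <- ts1$summary$c_volume_uM[which.min(abs(ts1$times - 0.8))]
  cv2 <- ts2$summary$c_volume_uM[which.min(abs(ts2$times - 0.8))]
  expect_lt(abs(cv2 - cv1) / cv1, 0.02)
  # time at which the volume average falls below 1 uM (clearance summary)
  tcl <- function(ts) crossing_time(ts$times, ts$summary$c_volume_uM, 1)
  expect_lt(abs(tcl(ts2) - tcl(ts1)) / tcl(ts1), 0.02)
})

test_that("clearance accelerates with the pump cycle rate", {
  g <- default_geom()
  pr <- influx_protocol(record_duration = 60)
  tcl <- vapply(c(2000, 5000, 20000), function(phi) {
    ts <- solve_dynamic(g, pump_params(phi), buffer_params(0), pr,
                        n_shells = 20)
    crossing_time(ts$times, ts$summary$c_volume_uM, 1)
  }, numeric(1))
  expect_true(all(is.finite(tcl)))
  expect_true(all(diff(tcl) < 0))
})

test_that("field summaries are reproducible from the stored fields", {
  g <- default_geom()
  pr <- influx_protocol(record_duration = 5)
  ts <- solve_dynamic(g, pump_params(5000), buffer_params(100), pr,
                      n_shells = 20)
  mesh_vol <- diff((seq(0, g$radius, length.out = 21))^3)
  w <- mesh_vol / sum(mesh_vol)
  expect_equal(as.numeric(ts$ca %*% w), ts$summary$c_volume_uM,
               tolerance = 1e-9)
  expect_equal(pmax(ts$ca[, 20] + 0.5 * (ts$ca[, 20] - ts$ca[, 19]), 0),
               ts$summary$c_membrane_uM, tolerance = 1e-12)
})
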