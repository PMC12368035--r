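test_that("geometry derives radius and accessible volume from surface area", {
  g <- make_geometry(300, 0.3, 0)
  expect_equal(g$radius, sqrt(300 / (4 * pi)), tolerance = 1e-12)
  expect_equal(g$radius, 4.886, tolerance = 1e-3)
  expect_equal(g$surface_area, 4 * pi * g$radius^2, tolerance = 1e-9)
  expect_equal(g$accessible_volume, 0.3 * (4 / 3) * pi * g$radius^3,
               tolerance = 1e-12)
  expect_equal(g$accessible_volume, 146.6, tolerance = 1e-3)

  unit <- make_geometry(4 * pi, 1.0, 0)
  expect_equal(unit$radius, 1, tolerance = 1e-12)
})

test_that("geometry rejects invalid inputs", {
  expect_error(make_geometry(-300, 0.3), "surface_area")
  expect_error(make_geometry(0, 0.3), "surface_area")
  expect_error(make_geometry(300, 0), "accessible_fraction")
  expect_error(make_geometry(300, 1.2), "accessible_fraction")
  expect_error(make_geometry(300, 0.3, 5.0), "invalid geometry")
})

test_that("ion count converts to a well-mixed concentration rise", {
  g <- default_geom()
  expect_equal(uniform_concentration_increment(g, 1.2e6), 13.6,
               tolerance = 1e-2)
  expect_equal(uniform_concentration_increment(g, 0), 0)
  g1 <- make_geometry(300, 1.0, 0)
  expect_equal(uniform_concentration_increment(g1, 1.2e6), 4.08,
               tolerance = 1e-2)
})

test_that("count/concentration conversion round-trips and scales linearly", {
  g <- default_geom()
  const <- physical_constants()
  expect_equal(const$ions_per_uM_um3, 6.02214076e23 * 1e-6 * 1e-15,
               tolerance = 1e-6)
  for (conc in c(0.1, 1, 13.6, 500)) {
    ions <- conc * const$ions_per_uM_um3 * g$accessible_volume
    expect_equal(uniform_concentration_increment(g, ions), conc,
                 tolerance = 1e-12)
  }
  # linear in ions, inverse in accessible fraction
  expect_equal(uniform_concentration_increment(g, 2.4e6),
               2 * uniform_concentration_increment(g, 1.2e6),
               tolerance = 1e-12)
  g_half <- make_geometry(300, 0.15, 0)
  expect_equal(uniform_concentration_increment(g_half, 1.2e6),
               2 * uniform_concentration_increment(g, 1.2e6),
               tolerance = 1e-12)
})

test_that("parameter constructors validate and carry defaults", {
  p <- pump_params()
  expect_equal(p$c_half, 0.43)
  expect_equal(p$hill_n, 2)
  expect_equal(p$density, 50)
  expect_equal(p$resting_c0, 0.1)
  expect_error(pump_params(c_half = -1), "c_half")

  b <- buffer_params(1e4)
  expect_equal(b$kd, 0.4 / 2.7, tolerance = 1e-12)
  expect_error(buffer_params(-1), "buffer")

  pr <- influx_protocol()
  expect_equal(pr$total_influx, 1.2e6)
  expect_equal(influx_protocol(n_pulses = 5)$total_influx, 6e6)
  expect_error(influx_protocol(n_pulses = 0), "n_pulses")
})

test_that("parameter sets round-trip through flat JSON configs", {
  tmp <- withr::local_tempfile(fileext = ".json")
  for (obj in list(default_geom(), pump_params(20000),
                   buffer_params(100), influx_protocol(n_pulses = 2))) {
    write_param_config(obj, tmp)
    back <- read_param_config(tmp)
    common <- intersect(names(obj), names(back))
    expect_equal(back[common], obj[common], tolerance = 1e-12)
  }
})
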