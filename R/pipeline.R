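# Experiment orchestration from JSON-compatible run configurations. A
# config names the experiment kind and overrides any subset of the module
# parameters by section; a run echoes the fully resolved config into its
# summary so that re-running the echo reproduces all numeric outputs.

.default_config <- function() {
  list(
    experiment = "pulse",
    seed = 1,
    geometry = list(surface_area = 300, accessible_fraction = 0.3,
                    pipette_contact_radius = 1.0),
    pump = list(cycle_rate = 5000, density = 50, c_half = 0.43,
                hill_n = 2, resting_c0 = 0.1),
    buffer = list(b_total = 0, k_on = 2.7, k_off = 0.4, diff_coeff = 110),
    protocol = list(n_pulses = 1, pulse_duration = 0.8,
                    inter_pulse_gap = 2.0, ions_per_pulse = 1.2e6,
                    pre_potential = 70, pulse_potential = -60,
                    test_potential = 70, record_duration = 120),
    solver = list(d_ca = 220, n_shells = 30, n_r = 24, n_theta = 48),
    steady = list(c_pip = 10, v_min = -80, v_max = 240, v_step = 10),
    pulse = list(influx = "pulse", step_ca = 10, readout = "volume"),
    scan = list(rates = c(50, 500, 5000, 20000), mode = "steady",
                overlay_tol_mV = 10, reference_b_total = 1e4,
                tau_factor = 2),
    synth = list(noise_sigma = 0.02)
  )
}

.check_positive <- function(cfg, paths) {
  for (p in paths) {
    parts <- strsplit(p, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (is.null(val) || !is.numeric(val) || any(!is.finite(val)) ||
        any(val < 0)) {
      stop("config error: field '", p,
           "' must be a non-negative finite number", call. = FALSE)
    }
  }
}

#' Validate and resolve a run configuration
#'
#' Merges a (possibly partial) configuration over the package defaults and
#' validates field types and signs; violations are reported with the field
#' path (e.g. `pump.density`).
#'
#' @param config A named list, or a path to a JSON config file.
#' @return The fully resolved config list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- .default_config()
  for (nm in names(config)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(config[[nm]])) {
      utils::modifyList(cfg[[nm]], config[[nm]])
    } else config[[nm]]
  }
  kinds <- c("steady", "pulse", "scan", "calibrate", "synth")
  if (!is.character(cfg$experiment) || !cfg$experiment %in% kinds) {
    stop("config error: field 'experiment' must be one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  .check_positive(cfg, c(
    "geometry.surface_area", "geometry.accessible_fraction",
    "geometry.pipette_contact_radius",
    "pump.cycle_rate", "pump.density", "pump.c_half", "pump.hill_n",
    "pump.resting_c0",
    "buffer.b_total", "buffer.k_on", "buffer.k_off", "buffer.diff_coeff",
    "protocol.n_pulses", "protocol.pulse_duration",
    "protocol.ions_per_pulse", "protocol.record_duration",
    "solver.d_ca", "solver.n_shells"
  ))
  cfg
}

.cfg_objects <- function(cfg) {
  list(
    geometry = do.call(make_geometry, cfg$geometry),
    pump = do.call(pump_params, cfg$pump),
    buffer = do.call(buffer_params, cfg$buffer),
    protocol = do.call(influx_protocol, cfg$protocol)
  )
}

#' Run an experiment from a configuration
#'
#' Executes the experiment named by the config (`steady`, `pulse`, `scan`,
#' `calibrate` or `synth`) and returns a JSON-compatible summary including
#' the resolved config echo. With an output directory, traces/curves are
#' written as tab-separated text, the summary as JSON and a plain-text log.
#'
#' @param config A named list or path to a JSON config file (see
#'   [resolve_config()]).
#' @param out_dir Optional output directory.
#' @param truth Gating truth set used by the experiments (defaults to
#'   [default_truth()]).
#' @return The summary list, invisibly.
#' @export
run_experiment <- function(config = list(), out_dir = NULL,
                           truth = default_truth()) {
  cfg <- resolve_config(config)
  t0 <- Sys.time()
  obj <- .cfg_objects(cfg)
  v_grid <- seq(cfg$steady$v_min, cfg$steady$v_max, by = cfg$steady$v_step)
  artifacts <- list()

  result <- switch(
    cfg$experiment,
    steady = {
      curve <- run_steady_experiment(obj$geometry, obj$pump,
                                     truth$bk_steady,
                                     c_pip = cfg$steady$c_pip,
                                     v_grid = v_grid,
                                     d_ca = cfg$solver$d_ca,
                                     n_r = cfg$solver$n_r,
                                     n_theta = cfg$solver$n_theta)
      artifacts$curve <- data.frame(voltage_mV = curve$voltages,
                                    g_norm = curve$g_norm)
      list(vh_mV = curve$fitted_vh, k_mV = curve$fitted_k,
           fit_rmse = curve$fit_rmse,
           membrane_ca_mean_uM = attr(curve, "field")$membrane_mean)
    },
    pulse = {
      tr <- run_pulse_experiment(obj$geometry, obj$pump, obj$buffer,
                                 obj$protocol, truth$bk_kinetic,
                                 influx = cfg$pulse$influx,
                                 step_ca = cfg$pulse$step_ca,
                                 readout = cfg$pulse$readout,
                                 d_ca = cfg$solver$d_ca,
                                 n_shells = cfg$solver$n_shells)
      artifacts$trace <- data.frame(time_ms = tr$times, p_open = tr$values)
      artifacts$field <- attr(tr, "field_series")$summary
      list(tau_decay_ms = tr$tau_decay,
           fit_failed = tr$fit$failed,
           peak_p_open = max(tr$values),
           fit_window_ms = tr$fit_window)
    },
    scan = {
      sc <- scan_pump_rates(cfg$scan$rates, mode = cfg$scan$mode,
                            geometry = obj$geometry, pump = obj$pump,
                            buffer = obj$buffer, protocol = obj$protocol,
                            bk_steady = truth$bk_steady,
                            bk_kinetic = truth$bk_kinetic,
                            c_pip = cfg$steady$c_pip, v_grid = v_grid,
                            overlay_tol_mV = cfg$scan$overlay_tol_mV,
                            reference_b_total = cfg$scan$reference_b_total,
                            tau_factor = cfg$scan$tau_factor,
                            influx = cfg$pulse$influx,
                            d_ca = cfg$solver$d_ca,
                            n_r = cfg$solver$n_r,
                            n_theta = cfg$solver$n_theta)
      artifacts$scan <- sc$table
      list(table = sc$table, reference = sc$reference,
           minimal_sufficient_rate = sc$minimal_sufficient_rate)
    },
    calibrate = {
      curves <- gen_activation_curves(truth,
                                      noise_sigma = cfg$synth$noise_sigma,
                                      seed = cfg$seed)
      fit <- calibrate_steady(curves, seed = cfg$seed)
      list(vh_by_c = fit$report$vh_by_c,
           rmse_total = fit$report$rmse_total, refused = fit$refused)
    },
    synth = {
      if (is.null(out_dir)) {
        stop("config error: synth experiment requires out_dir",
             call. = FALSE)
      }
      man <- write_synthetic_dataset(file.path(out_dir, "dataset"),
                                     truth = truth, seed = cfg$seed,
                                     noise_sigma = cfg$synth$noise_sigma)
      list(manifest = man)
    }
  )

  summary <- list(
    experiment = cfg$experiment,
    result = result,
    config = cfg,
    seed = cfg$seed,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("caclear"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(artifacts)) {
      utils::write.table(artifacts[[nm]],
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(
      c(paste("experiment:", cfg$experiment),
        paste("seed:", cfg$seed),
        paste("wall_time_s:", signif(summary$wall_time_s, 4)),
        paste("config echo: summary.json")),
      file.path(out_dir, "run.log")
    )
  }
  invisible(summary)
}
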