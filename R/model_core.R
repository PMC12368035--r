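#' Physical constants at a stated temperature
#'
#' Bundles the two conversion constants the solvers need: the Boltzmann
#' voltage factor F/RT (used in the exponential voltage dependence of channel
#' gating) and the count-to-concentration conversion for calcium ions.
#'
#' @param temperature_K Absolute temperature in kelvin. Defaults to 295 K
#'   (room temperature, at which whole-cell recordings of this kind are done).
#' @return An object of class `ca_constants` with fields
#'   `temperature_K`, `faraday_over_RT` (per volt), `faraday_over_RT_mV`
#'   (per millivolt) and `ions_per_uM_um3` (ions per cubic micrometre per
#'   micromolar, Avogadro x 1e-6 mol/L x 1e-15 L/um^3).
#' @export
physical_constants <- function(temperature_K = 295) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      temperature_K <= 0) {
    stop("temperature_K must be a single positive number", call. = FALSE)
  }
  f_over_rt <- 96485.33212 / (8.314462618 * temperature_K)
  structure(
    list(
      temperature_K = temperature_K,
      faraday_over_RT = f_over_rt,
      faraday_over_RT_mV = f_over_rt / 1000,
      ions_per_uM_um3 = 602.214076
    ),
    class = "ca_constants"
  )
}

#' Spherical cell geometry
#'
#' Builds the model-cell geometry from its membrane surface area. The cell is
#' a sphere; only a fraction of the enclosed volume is accessible to free
#' diffusion (the rest is occupied by organelles and macromolecules). An
#' optional pipette contact patch (for whole-cell recordings) is described by
#' the radius of a disc of equal area.
#'
#' @param surface_area Membrane surface area in square micrometres.
#' @param accessible_fraction Fraction of the geometric cell volume that is
#'   freely diffusible, in (0, 1].
#' @param pipette_contact_radius Radius (micrometres) of the disc-equivalent
#'   pipette contact patch; 0 when no pipette is attached.
#' @return An object of class `ca_geometry` with fields `surface_area`,
#'   `radius`, `accessible_fraction`, `accessible_volume` and
#'   `pipette_contact_radius`.
#' @examples
#' geom <- make_geometry(300, 0.3)
#' geom$radius             # ~4.886 um
#' geom$accessible_volume  # ~146.6 um^3
#' @export
make_geometry <- function(surface_area = 300, accessible_fraction = 0.3,
                          pipette_contact_radius = 0) {
  if (!is.numeric(surface_area) || length(surface_area) != 1L ||
      !is.finite(surface_area) || surface_area <= 0) {
    stop("invalid geometry: surface_area must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(accessible_fraction) || length(accessible_fraction) != 1L ||
      accessible_fraction <= 0 || accessible_fraction > 1) {
    stop("invalid geometry: accessible_fraction must lie in (0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(pipette_contact_radius) ||
      length(pipette_contact_radius) != 1L || pipette_contact_radius < 0) {
    stop("invalid geometry: pipette_contact_radius must be >= 0",
         call. = FALSE)
  }
  radius <- sqrt(surface_area / (4 * pi))
  if (pipette_contact_radius >= radius) {
    stop("invalid geometry: pipette_contact_radius (",
         pipette_contact_radius, " um) must be smaller than the cell radius (",
         signif(radius, 4), " um)", call. = FALSE)
  }
  structure(
    list(
      surface_area = surface_area,
      radius = radius,
      accessible_fraction = accessible_fraction,
      accessible_volume = accessible_fraction * (4 / 3) * pi * radius^3,
      pipette_contact_radius = pipette_contact_radius
    ),
    class = "ca_geometry"
  )
}

#' Pump transport parameters
#'
#' Parameters of the Hill-type calcium efflux carried by PMCA pump complexes:
#' each pump extrudes one calcium ion per transport cycle, at a cycle rate
#' modulated by the local free calcium concentration through a Hill function.
#' A constant inward leak flux, fixed so that the net membrane flux vanishes
#' at the resting concentration, makes `resting_c0` a genuine steady state.
#'
#' @param cycle_rate Full transport cycles per second of one pump (phi).
#' @param density Pumps per square micrometre of membrane (rho).
#' @param c_half Free calcium concentration (micromolar) at half-maximal
#'   transport activity.
#' @param hill_n Hill coefficient of the activity curve.
#' @param resting_c0 Resting free calcium concentration in micromolar.
#' @return An object of class `ca_pump`.
#' @export
pump_params <- function(cycle_rate = 5000, density = 50, c_half = 0.43,
                        hill_n = 2, resting_c0 = 0.1) {
  vals <- c(cycle_rate = cycle_rate, density = density, c_half = c_half,
            hill_n = hill_n, resting_c0 = resting_c0)
  if (!all(is.finite(vals))) {
    stop("pump parameters must all be finite numbers", call. = FALSE)
  }
  if (cycle_rate < 0 || density < 0) {
    stop("pump cycle_rate and density must be >= 0", call. = FALSE)
  }
  if (c_half <= 0 || hill_n <= 0 || resting_c0 <= 0) {
    stop("pump c_half, hill_n and resting_c0 must be > 0", call. = FALSE)
  }
  structure(as.list(vals), class = "ca_pump")
}

#' Mobile buffer (EGTA) parameters
#'
#' Second-order binding kinetics of a mobile calcium chelator. The defaults
#' are literature-typical EGTA kinetics near pH 7.3; the total concentration
#' is experiment-specific (0, 0.1 or 10 mM in the conditions modelled here).
#'
#' @param b_total Total buffer concentration in micromolar.
#' @param k_on Binding rate in per-micromolar-per-second.
#' @param k_off Unbinding rate in per-second.
#' @param diff_coeff Buffer diffusion coefficient in square micrometres per
#'   second.
#' @return An object of class `ca_buffer`, with the dissociation constant
#'   `kd` (micromolar) attached when `k_on > 0`.
#' @export
buffer_params <- function(b_total = 0, k_on = 2.7, k_off = 0.4,
                          diff_coeff = 110) {
  vals <- c(b_total = b_total, k_on = k_on, k_off = k_off,
            diff_coeff = diff_coeff)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop("buffer parameters must all be finite and >= 0", call. = FALSE)
  }
  out <- as.list(vals)
  out$kd <- if (k_on > 0) k_off / k_on else NA_real_
  structure(out, class = "ca_buffer")
}

#' Voltage and calcium-influx pulse protocol
#'
#' Describes the pulsed-influx protocol: from a depolarized pre-potential
#' (at which the calcium channels are open but carry no net flux), one or
#' more brief repolarization pulses drive a fixed number of calcium ions
#' into the cell; the readout current is measured at the test potential.
#' Influx pulse `k` (0-based) occupies the window
#' `[k*(pulse_duration + inter_pulse_gap), k*(...) + pulse_duration)` ms.
#'
#' @param n_pulses Number of influx pulses (>= 1).
#' @param pulse_duration Influx pulse duration in milliseconds.
#' @param inter_pulse_gap Non-influx interval between pulses, milliseconds.
#' @param ions_per_pulse Calcium ions entering the cell per pulse.
#' @param pre_potential,pulse_potential,test_potential Membrane potentials in
#'   millivolts before, during and after the influx pulses.
#' @param record_duration Total simulated/recorded time in milliseconds,
#'   counted from the start of the first pulse.
#' @return An object of class `ca_protocol` with the derived field
#'   `total_influx` (ions).
#' @export
influx_protocol <- function(n_pulses = 1, pulse_duration = 0.8,
                            inter_pulse_gap = 2.0, ions_per_pulse = 1.2e6,
                            pre_potential = 70, pulse_potential = -60,
                            test_potential = 70, record_duration = 120) {
  if (n_pulses < 1 || n_pulses != round(n_pulses)) {
    stop("n_pulses must be a positive integer", call. = FALSE)
  }
  if (pulse_duration <= 0 || ions_per_pulse <= 0 || inter_pulse_gap < 0 ||
      record_duration <= 0) {
    stop("pulse_duration, ions_per_pulse and record_duration must be > 0",
         call. = FALSE)
  }
  structure(
    list(
      n_pulses = as.integer(n_pulses),
      pulse_duration = pulse_duration,
      inter_pulse_gap = inter_pulse_gap,
      ions_per_pulse = ions_per_pulse,
      pre_potential = pre_potential,
      pulse_potential = pulse_potential,
      test_potential = test_potential,
      record_duration = record_duration,
      total_influx = n_pulses * ions_per_pulse
    ),
    class = "ca_protocol"
  )
}

#' Well-mixed concentration rise for a given ion load
#'
#' The unbuffered, instantaneously mixed increase in free calcium produced by
#' delivering `ions` calcium ions into the accessible cell volume.
#'
#' @param geometry A `ca_geometry` object.
#' @param ions Number of ions (>= 0).
#' @return Concentration increment in micromolar.
#' @examples
#' uniform_concentration_increment(make_geometry(300, 0.3), 1.2e6)  # ~13.6 uM
#' @export
uniform_concentration_increment <- function(geometry, ions) {
  stopifnot(inherits(geometry, "ca_geometry"))
  if (!is.numeric(ions) || any(ions < 0)) {
    stop("ions must be >= 0", call. = FALSE)
  }
  ions / (physical_constants()$ions_per_uM_um3 * geometry$accessible_volume)
}

# --- flat key-value config serialization ------------------------------------

.ca_param_fields <- list(
  ca_geometry = c("surface_area", "accessible_fraction",
                  "pipette_contact_radius"),
  ca_pump     = c("cycle_rate", "density", "c_half", "hill_n", "resting_c0"),
  ca_buffer   = c("b_total", "k_on", "k_off", "diff_coeff"),
  ca_protocol = c("n_pulses", "pulse_duration", "inter_pulse_gap",
                  "ions_per_pulse", "pre_potential", "pulse_potential",
                  "test_potential", "record_duration")
)

.ca_param_ctor <- list(
  ca_geometry = make_geometry, ca_pump = pump_params,
  ca_buffer = buffer_params, ca_protocol = influx_protocol
)

#' Write a parameter set to a flat JSON config file
#'
#' Serializes a geometry, pump, buffer or protocol parameter object to a flat
#' key-value JSON file whose keys are exactly the constructor field names, so
#' the file round-trips through [read_param_config()].
#'
#' @param params A `ca_geometry`, `ca_pump`, `ca_buffer` or `ca_protocol`
#'   object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_param_config <- function(params, path) {
  cls <- intersect(class(params), names(.ca_param_fields))
  if (length(cls) != 1L) {
    stop("params must be one of: ",
         paste(names(.ca_param_fields), collapse = ", "), call. = FALSE)
  }
  out <- params[.ca_param_fields[[cls]]]
  out$.type <- cls
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter set from a flat JSON config file
#'
#' @param path A file written by [write_param_config()].
#' @return The reconstructed parameter object (validated by its constructor).
#' @export
read_param_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- raw$.type
  if (is.null(cls) || !cls %in% names(.ca_param_fields)) {
    stop("config file does not carry a recognised .type field", call. = FALSE)
  }
  do.call(.ca_param_ctor[[cls]], raw[.ca_param_fields[[cls]]])
}
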