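#' Hill activity of the pump at a given free calcium concentration
#'
#' Fraction of maximal transport activity, `c^n / (c^n + c_half^n)`;
#' monotone nondecreasing in `c`, 0 at `c = 0`, 1/2 at `c = c_half`.
#'
#' @param c Free calcium concentration(s), micromolar (>= 0).
#' @param pump A `ca_pump` object.
#' @return Dimensionless activity in \[0, 1).
#' @export
hill_activity <- function(c, pump) {
  stopifnot(inherits(pump, "ca_pump"))
  if (any(c < 0)) stop("free calcium concentration must be >= 0",
                       call. = FALSE)
  cn <- c^pump$hill_n
  cn / (cn + pump$c_half^pump$hill_n)
}

#' Pump-mediated calcium efflux density
#'
#' Outward flux of calcium carried by the pumps,
#' `cycle_rate * density * hill_activity(c)`, saturating at
#' `cycle_rate * density`.
#'
#' @inheritParams hill_activity
#' @return Efflux density in ions per square micrometre per second.
#' @export
pump_outflux_density <- function(c, pump) {
  pump$cycle_rate * pump$density * hill_activity(c, pump)
}

#' Constant leak influx density pinning the resting state
#'
#' The leak is a constant inward calcium flux equal to the pump efflux at the
#' resting concentration, so the net membrane flux at `c = resting_c0` is
#' exactly zero and the rest state is a genuine equilibrium.
#'
#' @param pump A `ca_pump` object.
#' @return Influx density in ions per square micrometre per second.
#' @export
leak_influx_density <- function(pump) {
  pump_outflux_density(pump$resting_c0, pump)
}

#' Voltage-gated calcium influx density at time t
#'
#' During each influx pulse the experimentally prescribed number of ions per
#' pulse enters uniformly over the membrane over the pulse duration; the flux
#' is zero outside the pulse windows. Pulse `k` (0-based) occupies
#' `[k*(pulse_duration + inter_pulse_gap), k*(...) + pulse_duration)` ms.
#'
#' @param protocol A `ca_protocol` object.
#' @param t Time(s) in milliseconds since the start of the first pulse.
#' @param geometry A `ca_geometry` object.
#' @return Influx density in ions per square micrometre per second
#'   (vectorized over `t`).
#' @export
cav_influx_density <- function(protocol, t, geometry) {
  stopifnot(inherits(protocol, "ca_protocol"),
            inherits(geometry, "ca_geometry"))
  period <- protocol$pulse_duration + protocol$inter_pulse_gap
  phase <- t - period * pmin(floor(t / period), protocol$n_pulses - 1)
  on <- t >= 0 & phase >= 0 & phase < protocol$pulse_duration &
    t < (protocol$n_pulses - 1) * period + protocol$pulse_duration
  dens <- protocol$ions_per_pulse /
    (protocol$pulse_duration * 1e-3 * geometry$surface_area)
  ifelse(on, dens, 0)
}

#' Membrane potential prescribed by the protocol at time t
#'
#' Pulse potential inside influx windows, test potential between and after
#' pulses, pre-potential for negative times.
#'
#' @inheritParams cav_influx_density
#' @return Membrane potential(s) in millivolts (vectorized over `t`).
#' @export
protocol_voltage <- function(protocol, t) {
  stopifnot(inherits(protocol, "ca_protocol"))
  period <- protocol$pulse_duration + protocol$inter_pulse_gap
  phase <- t - period * pmin(floor(t / period), protocol$n_pulses - 1)
  on <- t >= 0 & phase >= 0 & phase < protocol$pulse_duration &
    t < (protocol$n_pulses - 1) * period + protocol$pulse_duration
  out <- ifelse(on, protocol$pulse_potential, protocol$test_potential)
  out[t < 0] <- protocol$pre_potential
  out
}
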