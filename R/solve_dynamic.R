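# Dynamic (pulsed-influx) reaction-diffusion problem on the spherical cell.
#
# Spherical symmetry: the influx is prescribed as a surface-averaged flux
# density, so the dynamic problem carries no angular structure and reduces to
# a 1D radial finite-volume discretization. Concentrations are defined per
# accessible volume; the accessible fraction cancels in the diffusion terms
# (both shell volumes and face areas scale with it) and enters only in the
# conversion of membrane ion fluxes to concentration rates.

.radial_mesh <- function(radius, n_shells) {
  dr <- radius / n_shells
  r_face <- seq(0, radius, length.out = n_shells + 1)
  list(
    dr = dr,
    r_center = (r_face[-1] + r_face[-(n_shells + 1)]) / 2,
    area_face = 4 * pi * r_face^2,                       # index j+1 = face j
    vol_shell = (4 / 3) * pi * diff(r_face^3)
  )
}

.default_dynamic_times <- function(protocol) {
  period <- protocol$pulse_duration + protocol$inter_pulse_gap
  t_pulses_end <- (protocol$n_pulses - 1) * period + protocol$pulse_duration
  t_end <- protocol$record_duration
  tt <- c(
    seq(0, min(t_pulses_end + 2, t_end), by = 0.02),
    if (t_end > t_pulses_end + 2) seq(t_pulses_end + 2, min(20, t_end), by = 0.1),
    if (t_end > 20) seq(20, t_end, by = 0.25)
  )
  sort(unique(round(c(tt, t_end), 9)))
}

.influx_breaks <- function(protocol) {
  period <- protocol$pulse_duration + protocol$inter_pulse_gap
  k <- seq_len(protocol$n_pulses) - 1
  br <- round(c(k * period, k * period + protocol$pulse_duration), 9)
  sort(unique(c(0, br[br < protocol$record_duration],
                protocol$record_duration)))
}

#' Solve the dynamic calcium/buffer reaction-diffusion problem
#'
#' Integrates the coupled free-calcium and free-buffer fields on a radial
#' finite-volume mesh of the spherical cell. The membrane boundary carries
#' the voltage-gated influx (during pulse windows), the constant leak, and
#' the Hill-type pump efflux; in the bulk, calcium and buffer react with
#' second-order binding kinetics and diffuse with their own coefficients.
#' The integration starts from rest (calcium at `resting_c0` everywhere and
#' buffer at binding equilibrium with it) unless `initial_ca` prescribes a
#' homogeneous free-calcium starting level (used to emulate the state at the
#' end of an influx pulse directly; the buffer still starts at its resting
#' equilibrium).
#'
#' @param geometry A `ca_geometry` object.
#' @param pump A `ca_pump` object (use `cycle_rate = 0` for pump-free runs).
#' @param buffer A `ca_buffer` object (`b_total = 0` for unbuffered runs).
#' @param protocol A `ca_protocol` object; set `n_pulses`/`ions_per_pulse`
#'   through it. When `initial_ca` is given the influx term is disabled and
#'   the protocol only provides the record duration and potentials.
#' @param d_ca Effective calcium diffusion coefficient, um^2/s.
#' @param n_shells Number of radial finite-volume shells.
#' @param initial_ca Optional homogeneous initial free calcium (micromolar).
#' @param times Optional output time grid (ms); a pulse-resolving default is
#'   built from the protocol otherwise.
#' @param rtol,atol Integrator tolerances (passed to [deSolve::lsoda()]).
#' @param constants A `ca_constants` object.
#' @return An object of class `ca_field_series`: radial node positions,
#'   matrices of free calcium and free buffer over time, and a summary data
#'   frame with columns `time_ms`, `c_volume_uM`, `c_membrane_uM`,
#'   `b_free_uM`.
#' @export
solve_dynamic <- function(geometry, pump, buffer, protocol, d_ca = 220,
                          n_shells = 30, initial_ca = NULL, times = NULL,
                          rtol = 1e-8, atol = 1e-10,
                          constants = physical_constants()) {
  stopifnot(inherits(geometry, "ca_geometry"), inherits(pump, "ca_pump"),
            inherits(buffer, "ca_buffer"), inherits(protocol, "ca_protocol"))
  mesh <- .radial_mesh(geometry$radius, n_shells)
  n <- n_shells
  ipuu <- constants$ions_per_uM_um3
  af <- geometry$accessible_fraction
  with_influx <- is.null(initial_ca)

  c0 <- if (with_influx) pump$resting_c0 else initial_ca
  b0 <- if (buffer$b_total > 0) {
    buffer$b_total * buffer$k_off /
      (buffer$k_off + buffer$k_on * pump$resting_c0)
  } else 0
  y0 <- c(rep(c0, n), rep(b0, n))

  j_leak <- leak_influx_density(pump)
  a_in <- mesh$area_face[2:n]          # interior faces
  vol <- mesh$vol_shell
  dr <- mesh$dr
  dc_ms <- d_ca / 1000                 # um^2/ms
  db_ms <- buffer$diff_coeff / 1000
  kon_ms <- buffer$k_on / 1000
  koff_ms <- buffer$k_off / 1000
  # membrane ion flux (ions/um^2/s) -> concentration rate in outer shell
  memb_scale <- geometry$surface_area / (1000 * ipuu * af * vol[n])

  rhs <- function(t, y, p) {
    ca <- pmax(y[1:n], 0)
    bf <- pmax(y[(n + 1):(2 * n)], 0)
    react <- -kon_ms * ca * bf + koff_ms * (buffer$b_total - bf)
    gc <- dc_ms * a_in * diff(ca) / dr
    dca <- (c(gc, 0) - c(0, gc)) / vol + react
    j_cav <- if (with_influx) cav_influx_density(protocol, t, geometry) else 0
    # pump senses calcium at the membrane face (second-order extrapolation
    # from the two outermost shells), not at the outer cell centre
    c_face <- max(ca[n] + 0.5 * (ca[n] - ca[n - 1]), 0)
    j_net <- j_cav + j_leak - pump_outflux_density(c_face, pump)
    dca[n] <- dca[n] + j_net * memb_scale
    if (buffer$b_total > 0) {
      gb <- db_ms * a_in * diff(bf) / dr
      dbf <- (c(gb, 0) - c(0, gb)) / vol + react
    } else {
      dbf <- rep(0, n)
    }
    list(c(dca, dbf))
  }

  out_times <- if (is.null(times)) .default_dynamic_times(protocol) else
    sort(unique(times))
  breaks <- if (with_influx) .influx_breaks(protocol) else
    range(out_times)
  breaks <- sort(unique(c(breaks, range(out_times))))

  rows <- list()
  y <- y0
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    tt <- sort(unique(c(t0, out_times[out_times > t0 & out_times <= t1], t1)))
    sol <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% out_times
    if (s == 1) keep[1] <- 0 %in% out_times
    else keep[1] <- FALSE  # boundary already emitted by previous segment
    rows[[s]] <- sol[keep, , drop = FALSE]
  }
  sol <- do.call(rbind, rows)
  tms <- sol[, 1]
  ca <- sol[, 1 + (1:n), drop = FALSE]
  bf <- sol[, 1 + n + (1:n), drop = FALSE]
  if (min(ca) < -1e-6 || min(bf) < -1e-6) {
    stop("integration error: positivity violated (min free Ca ",
         signif(min(ca), 3), " uM)", call. = FALSE)
  }
  ca[ca < 0] <- 0
  bf[bf < 0] <- 0

  w <- vol / sum(vol)
  summary <- data.frame(
    time_ms = tms,
    c_volume_uM = as.numeric(ca %*% w),
    c_membrane_uM = pmax(ca[, n] + 0.5 * (ca[, n] - ca[, n - 1]), 0),
    b_free_uM = as.numeric(bf %*% w)
  )
  structure(
    list(
      times = tms, radii = mesh$r_center, ca = ca, buffer = bf,
      membrane_weights = geometry$surface_area, summary = summary,
      geometry = geometry, pump = pump, buffer_params = buffer,
      protocol = protocol, d_ca = d_ca, n_shells = n
    ),
    class = "ca_field_series"
  )
}

#' Well-mixed two-variable reference model
#'
#' Integrates the volume-averaged calcium/buffer ODE system with all membrane
#' fluxes scaled by surface-to-accessible-volume, i.e. the fast-diffusion
#' limit of [solve_dynamic()]. Used as an independent verification oracle for
#' the spatial solver.
#'
#' @inheritParams solve_dynamic
#' @return A data frame with columns `time_ms`, `c_uM`, `b_free_uM`.
#' @export
wellmixed_reference <- function(geometry, pump, buffer, protocol,
                                initial_ca = NULL, times = NULL,
                                rtol = 1e-10, atol = 1e-12,
                                constants = physical_constants()) {
  stopifnot(inherits(geometry, "ca_geometry"), inherits(pump, "ca_pump"),
            inherits(buffer, "ca_buffer"), inherits(protocol, "ca_protocol"))
  with_influx <- is.null(initial_ca)
  c0 <- if (with_influx) pump$resting_c0 else initial_ca
  b0 <- if (buffer$b_total > 0) {
    buffer$b_total * buffer$k_off /
      (buffer$k_off + buffer$k_on * pump$resting_c0)
  } else 0
  j_leak <- leak_influx_density(pump)
  scale <- geometry$surface_area /
    (1000 * constants$ions_per_uM_um3 * geometry$accessible_volume)
  kon_ms <- buffer$k_on / 1000
  koff_ms <- buffer$k_off / 1000

  rhs <- function(t, y, p) {
    ca <- max(y[1], 0); bf <- max(y[2], 0)
    react <- -kon_ms * ca * bf + koff_ms * (buffer$b_total - bf)
    j_cav <- if (with_influx) cav_influx_density(protocol, t, geometry) else 0
    dca <- (j_cav + j_leak - pump_outflux_density(ca, pump)) * scale + react
    list(c(dca, react))
  }
  out_times <- if (is.null(times)) .default_dynamic_times(protocol) else
    sort(unique(times))
  breaks <- if (with_influx) .influx_breaks(protocol) else range(out_times)
  breaks <- sort(unique(c(breaks, range(out_times))))
  rows <- list(); y <- c(c0, b0)
  for (s in seq_len(length(breaks) - 1)) {
    tt <- sort(unique(c(breaks[s],
                        out_times[out_times > breaks[s] &
                                    out_times <= breaks[s + 1]],
                        breaks[s + 1])))
    sol <- deSolve::lsoda(y, tt, rhs, parms = NULL, rtol = rtol, atol = atol)
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% out_times
    if (s > 1) keep[1] <- FALSE else keep[1] <- 0 %in% out_times
    rows[[s]] <- sol[keep, , drop = FALSE]
  }
  sol <- do.call(rbind, rows)
  data.frame(time_ms = sol[, 1], c_uM = pmax(sol[, 2], 0),
             b_free_uM = pmax(sol[, 3], 0))
}

#' Total calcium content (free plus buffer-bound) of a field series
#'
#' Ion count over the accessible volume at each stored time; constant in a
#' closed system (no influx, no pump, no leak).
#'
#' @param ts A `ca_field_series` object.
#' @return Numeric vector of ion counts, one per stored time.
#' @export
total_calcium_ions <- function(ts, constants = physical_constants()) {
  stopifnot(inherits(ts, "ca_field_series"))
  mesh <- .radial_mesh(ts$geometry$radius, ts$n_shells)
  vol_acc <- mesh$vol_shell * ts$geometry$accessible_fraction
  bound <- ts$buffer_params$b_total - ts$buffer
  as.numeric((ts$ca + bound) %*% vol_acc) * constants$ions_per_uM_um3
}

#' Export the summary of a field series as delimited text
#'
#' @param ts A `ca_field_series` object.
#' @param path Output path (tab-separated, columns `time_ms`, `c_volume_uM`,
#'   `c_membrane_uM`, `b_free_uM`).
#' @return `path`, invisibly.
#' @export
export_field_summary <- function(ts, path) {
  stopifnot(inherits(ts, "ca_field_series"))
  utils::write.table(ts$summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
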