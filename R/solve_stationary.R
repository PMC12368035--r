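# Stationary pipette-source diffusion problem.
#
# Whole-cell configuration: the pipette clamps free calcium to c_pip over a
# polar spherical cap whose area equals a disc of the pipette contact radius
# (Dirichlet); over the remaining membrane the pumps extrude calcium against
# the constant leak (nonlinear flux balance, von Neumann). Laplace's equation
# is discretized by finite volumes on an axisymmetric (r, theta) mesh and the
# nonlinear boundary condition is resolved by a damped Newton iteration on
# the membrane concentration (the Hill flux is linearized into a Robin term
# at each step).

#' Solve the stationary calcium diffusion problem with a pipette source
#'
#' @param geometry A `ca_geometry` object with `pipette_contact_radius > 0`.
#' @param pump A `ca_pump` object.
#' @param c_pip Pipette free calcium concentration, micromolar (> 0).
#' @param d_ca Effective calcium diffusion coefficient, um^2/s.
#' @param n_r,n_theta Radial and polar mesh resolution.
#' @param tol Relative tolerance of the nonlinear boundary iteration.
#' @param max_iter Iteration cap; non-convergence raises an error carrying
#'   the last residual.
#' @param constants A `ca_constants` object.
#' @return An object of class `ca_field`: cell-centre node positions,
#'   the free-calcium field, membrane (outer non-pipette cell) values with
#'   their outer-face area weights, and the converged residual.
#' @export
solve_stationary <- function(geometry, pump, c_pip, d_ca = 220,
                             n_r = 48, n_theta = 96, tol = 1e-8,
                             max_iter = 500,
                             constants = physical_constants()) {
  stopifnot(inherits(geometry, "ca_geometry"), inherits(pump, "ca_pump"))
  if (geometry$pipette_contact_radius <= 0) {
    stop("stationary problem requires pipette_contact_radius > 0",
         call. = FALSE)
  }
  if (!is.numeric(c_pip) || length(c_pip) != 1L || c_pip <= 0) {
    stop("c_pip must be a single positive concentration", call. = FALSE)
  }
  R <- geometry$radius
  a <- geometry$pipette_contact_radius
  af <- geometry$accessible_fraction
  # polar cap of equal area: 2*pi*R^2*(1-cos(theta0)) = pi*a^2
  cos_t0 <- 1 - a^2 / (2 * R^2)

  th0 <- acos(cos_t0)
  # polar mesh with a face exactly on the cap edge and mild grading toward
  # the pole, so refinement converges cleanly despite the small cap
  n_cap <- max(4L, round(n_theta / 8))
  u <- seq(0, 1, length.out = n_cap + 1)
  s <- seq(0, 1, length.out = n_theta - n_cap + 1)
  # cells shrink quadratically toward the cap rim from both sides: the flux
  # density is singular at the rim of the Dirichlet patch
  th_face <- c(th0 * (1 - (1 - u)^2),
               (th0 + (pi - th0) * (2 * s^2 / (1 + s^2)))[-1])
  # radial mesh graded toward the membrane, where the pipette/pump boundary
  # layer lives
  w <- seq(0, 1, length.out = n_r + 1)
  r_face <- R * (1 - (1 - w)^1.7)
  r_c <- (r_face[-1] + r_face[-(n_r + 1)]) / 2
  th_c <- (th_face[-1] + th_face[-(n_theta + 1)]) / 2
  dmu <- -diff(cos(th_face))                       # positive, per theta band
  dr_cell <- diff(r_face)

  idx <- function(i, k) (k - 1L) * n_r + i         # i radial, k polar
  nn <- n_r * n_theta

  # transmissibilities: D * face_area / centre_distance (vectorized)
  ir <- rep(seq_len(n_r - 1), n_theta)             # radial faces
  kr <- rep(seq_len(n_theta), each = n_r - 1)
  t_rad <- d_ca * 2 * pi * r_face[ir + 1]^2 * dmu[kr] /
    ((dr_cell[ir] + dr_cell[ir + 1]) / 2)
  ip <- rep(seq_len(n_r), n_theta - 1)             # polar faces
  kp <- rep(seq_len(n_theta - 1), each = n_r)
  t_pol <- d_ca * pi * sin(th_face[kp + 1]) *
    (r_face[ip + 1]^2 - r_face[ip]^2) / (r_c[ip] * (th_c[kp + 1] - th_c[kp]))
  ii <- c(idx(ir, kr), idx(ip, kp))
  jj <- c(idx(ir + 1, kr), idx(ip, kp + 1))
  tv <- c(t_rad, t_pol)
  tr <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(tv, tv),
                             dims = c(nn, nn))
  lap <- Matrix::Diagonal(x = Matrix::rowSums(tr)) - tr

  outer_cells <- idx(n_r, seq_len(n_theta))
  outer_area <- 2 * pi * R^2 * dmu                 # outer face area per band
  on_pip <- th_c < acos(cos_t0)
  if (!any(on_pip)) on_pip[1] <- TRUE              # cap always resolved
  t_dir <- d_ca * outer_area / (dr_cell[n_r] / 2)  # half-cell Dirichlet link

  ipuu <- constants$ions_per_uM_um3
  j_leak <- leak_influx_density(pump)
  j_out <- function(cc) pump_outflux_density(cc, pump) - j_leak
  flux_scale <- 1 / (ipuu * af)                    # ions -> concentration

  # stabilized Picard iteration: the nonlinear pump flux enters through a
  # fixed Robin coefficient kappa that bounds its slope (Lipschitz constant
  # of the Hill flux), which makes the boundary map contractive for the
  # monotone flux and lets the system matrix be assembled once
  n_h <- pump$hill_n; ch <- pump$c_half
  c_star <- ch * ((n_h - 1) / (n_h + 1))^(1 / n_h)
  kappa <- if (pump$cycle_rate * pump$density > 0) {
    pump$cycle_rate * pump$density *
      n_h * c_star^(n_h - 1) * ch^n_h / (c_star^n_h + ch^n_h)^2
  } else 0
  diag_add <- numeric(nn); rhs_dir <- numeric(nn)
  diag_add[outer_cells[on_pip]] <- t_dir[on_pip]
  rhs_dir[outer_cells[on_pip]] <- t_dir[on_pip] * c_pip
  pump_cells <- outer_cells[!on_pip]
  diag_add[pump_cells] <- outer_area[!on_pip] * flux_scale * kappa
  A <- lap + Matrix::Diagonal(x = diag_add)

  cc <- rep(c_pip, nn)                             # initialization at c_pip
  resid <- Inf
  for (it in seq_len(max_iter)) {
    c_mem <- pmax(cc[outer_cells], 0)
    rhs <- rhs_dir
    rhs[pump_cells] <- -outer_area[!on_pip] * flux_scale *
      (j_out(c_mem[!on_pip]) - kappa * c_mem[!on_pip])
    c_new <- as.numeric(Matrix::solve(A, rhs))
    resid <- max(abs(c_new - cc)) / c_pip
    cc <- c_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop("stationary solver failed to converge (last residual ",
         signif(resid, 3), ")", call. = FALSE)
  }
  cc <- pmax(cc, 0)
  memb_ca <- cc[outer_cells][!on_pip]
  memb_w <- outer_area[!on_pip]
  structure(
    list(
      node_positions = cbind(
        r = rep(r_c, n_theta), theta = rep(th_c, each = n_r)
      ),
      free_ca = cc,
      free_buffer = NULL,
      membrane_ca = memb_ca,
      membrane_weights = memb_w,
      membrane_mean = sum(memb_ca * memb_w) / sum(memb_w),
      pipette_cap_cos = cos_t0,
      residual = resid,
      iterations = it,
      geometry = geometry, pump = pump, c_pip = c_pip, d_ca = d_ca,
      n_r = n_r, n_theta = n_theta
    ),
    class = "ca_field"
  )
}

#' Scalar flux-balance approximation of the stationary membrane concentration
#'
#' Equates the diffusion-limited disc-access delivery from the pipette,
#' `4 * D * a * (c_pip - c)` (in concentration-volume units, scaled to ion
#' counts by the accessible fraction), with the whole-surface net pump
#' efflux, and solves the resulting scalar equation for the far-membrane
#' concentration. This deliberately coarse closed-form balance serves as an
#' independent oracle for the axisymmetric solver.
#'
#' @inheritParams solve_stationary
#' @return Approximate membrane free calcium, micromolar.
#' @export
stationary_flux_balance <- function(geometry, pump, c_pip, d_ca = 220,
                                    constants = physical_constants()) {
  af <- geometry$accessible_fraction
  ipuu <- constants$ions_per_uM_um3
  a <- geometry$pipette_contact_radius
  deliver <- function(cc) 4 * d_ca * a * (c_pip - cc) * ipuu * af
  extrude <- function(cc) {
    (pump_outflux_density(cc, pump) - leak_influx_density(pump)) *
      geometry$surface_area
  }
  f <- function(cc) deliver(cc) - extrude(cc)
  if (f(pump$resting_c0) <= 0) return(pump$resting_c0)
  stats::uniroot(f, c(pump$resting_c0, c_pip), tol = 1e-12)$root
}
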