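# Ten-state gating model of the BK channel: five closed (C0..C4) and five
# open (O0..O4) states with four calcium binding sites. Opening/closing
# transitions C_i <-> O_i carry the voltage dependence; binding transitions
# along each tier carry the calcium dependence. The steady state has the
# closed form P_open = 1 / (1 + B(c) * L(0) * exp(-Q F V / RT)) with B(c)
# the ratio of the closed- and open-tier binding polynomials.

#' Steady-state (equilibrium-constant) BK gating parameters
#'
#' @param l0 Closed/open equilibrium constant at 0 mV with no calcium bound
#'   (larger values mean the unliganded channel rests closed).
#' @param gating_charge_q Effective gating charge, elementary charges.
#' @param kc,ko Stepwise calcium dissociation constants (micromolar, length
#'   4) of the closed and open tiers; `ko < kc` makes calcium binding favour
#'   opening.
#' @return An object of class `bk_steady`.
#' @export
bk_steady_params <- function(l0, gating_charge_q, kc, ko) {
  if (length(kc) != 4L || length(ko) != 4L) {
    stop("kc and ko must each hold 4 dissociation constants", call. = FALSE)
  }
  if (any(c(l0, gating_charge_q, kc, ko) <= 0) ||
      !all(is.finite(c(l0, gating_charge_q, kc, ko)))) {
    stop("all BK steady parameters must be positive and finite",
         call. = FALSE)
  }
  structure(
    list(l0 = l0, gating_charge_q = gating_charge_q,
         kc = as.numeric(kc), ko = as.numeric(ko)),
    class = "bk_steady"
  )
}

.binding_poly <- function(c, k) {
  # 1 + c/K1 + c^2/(K1 K2) + c^3/(K1 K2 K3) + c^4/(K1 K2 K3 K4)
  cp <- cumprod(k)
  1 + c / cp[1] + c^2 / cp[2] + c^3 / cp[3] + c^4 / cp[4]
}

#' Calcium-dependence factor B(c) of the steady-state model
#'
#' Ratio of the closed-tier to the open-tier fourth-order binding
#' polynomial; equals 1 at `c = 0` and tends to `prod(ko)/prod(kc)` as
#' `c` grows.
#'
#' @param c Free calcium concentration(s), micromolar (>= 0).
#' @param p A `bk_steady` object.
#' @return Dimensionless factor (vectorized over `c`).
#' @export
b_factor <- function(c, p) {
  stopifnot(inherits(p, "bk_steady"))
  if (any(c < 0)) stop("free calcium concentration must be >= 0",
                       call. = FALSE)
  .binding_poly(c, p$kc) / .binding_poly(c, p$ko)
}

#' Steady-state open probability of the BK channel
#'
#' `1 / (1 + B(c) * L(0) * exp(-Q F V / RT))`; strictly increasing in
#' voltage and, when the open tier binds calcium more tightly, in calcium.
#'
#' @param v Membrane potential(s), millivolts.
#' @param c Free calcium concentration(s), micromolar.
#' @param p A `bk_steady` object.
#' @param constants A `ca_constants` object.
#' @return Open probability in (0, 1), vectorized over `v` and/or `c`.
#' @export
popen_steady <- function(v, c, p, constants = physical_constants()) {
  stopifnot(inherits(p, "bk_steady"))
  1 / (1 + b_factor(c, p) * p$l0 *
         exp(-p$gating_charge_q * constants$faraday_over_RT_mV * v))
}

#' Steady-state activation curve over a voltage grid
#'
#' Open probability at fixed calcium over a voltage grid, normalized to its
#' maximum over the grid (the tail-current convention used for measured
#' conductance-voltage relations), optionally with a Boltzmann fit attached.
#'
#' @param p A `bk_steady` object.
#' @param c Fixed free calcium concentration, micromolar.
#' @param v_grid Voltage grid, millivolts (nonempty, increasing).
#' @param fit Fit a Boltzmann function to the normalized curve?
#' @param constants A `ca_constants` object.
#' @return An `activation_curve` object (see [fit_boltzmann()]): data frame
#'   fields `voltages`, `g_norm` plus `fitted_vh`, `fitted_k`, `fit_rmse`
#'   when fitted.
#' @export
steady_activation_curve <- function(p, c, v_grid, fit = TRUE,
                                    constants = physical_constants()) {
  if (length(v_grid) < 1L) stop("v_grid must be nonempty", call. = FALSE)
  v_grid <- sort(v_grid)
  po <- popen_steady(v_grid, c, p, constants)
  g <- po / max(po)
  curve <- structure(
    list(voltages = v_grid, g_norm = g, c_uM = c,
         fitted_vh = NA_real_, fitted_k = NA_real_, fit_rmse = NA_real_),
    class = "activation_curve"
  )
  if (fit) {
    bf <- fit_boltzmann(v_grid, g)
    curve$fitted_vh <- bf$vh; curve$fitted_k <- bf$k
    curve$fit_rmse <- bf$rmse
  }
  curve
}

#' Area-weighted surface average of the steady open probability
#'
#' Averages `popen_steady` over the membrane-local calcium values of a
#' stationary field, weighted by the membrane area each value represents.
#' This is the model analogue of a whole-cell conductance readout: the
#' channels are spread over the membrane and each senses its local calcium.
#'
#' @param field A `ca_field` object from [solve_stationary()], or any list
#'   with `membrane_ca` and `membrane_weights`.
#' @param v Membrane potential, millivolts.
#' @param p A `bk_steady` object.
#' @param constants A `ca_constants` object.
#' @return Scalar open probability.
#' @export
popen_surface_average <- function(field, v, p,
                                  constants = physical_constants()) {
  ca <- field$membrane_ca
  w <- field$membrane_weights
  if (is.null(ca) || length(ca) == 0L) {
    stop("field carries no membrane nodes", call. = FALSE)
  }
  if (length(w) == 1L) w <- rep(w, length(ca))
  sum(popen_steady(v, ca, p, constants) * w) / sum(w)
}

# --- kinetic (rate-constant) form -------------------------------------------

#' Kinetic (rate-constant) BK gating parameters
#'
#' Extends a steady-state parameter set with transition rates. Opening rates
#' at 0 mV are free per tier; closing rates are derived from the per-tier
#' equilibrium constants `L_i(0) = (1/L(0)) * prod(kc[1:i]/ko[1:i])`, and
#' calcium unbinding rates are derived from the dissociation constants with
#' matching statistical factors, so detailed balance holds around every
#' C_i - C_(i+1) - O_(i+1) - O_i loop by construction.
#'
#' @param steady A `bk_steady` object (equilibrium structure, pinned).
#' @param opening_rate0 Opening rates C_i -> O_i at 0 mV, per second,
#'   length 5 (tiers i = 0..4).
#' @param charge_split Fraction of the gating charge acting on the opening
#'   rate, in \[0, 1\].
#' @param ca_on_rate Calcium binding rate per free site,
#'   per-micromolar-per-second.
#' @return An object of class `bk_kinetic` carrying the derived
#'   `closing_rate0` tier rates and the embedded steady set.
#' @export
bk_kinetic_params <- function(steady, opening_rate0, charge_split = 0.5,
                              ca_on_rate = 300) {
  stopifnot(inherits(steady, "bk_steady"))
  if (length(opening_rate0) != 5L || any(opening_rate0 <= 0)) {
    stop("opening_rate0 must hold 5 positive per-tier rates", call. = FALSE)
  }
  if (charge_split < 0 || charge_split > 1) {
    stop("charge_split must lie in [0, 1]", call. = FALSE)
  }
  if (ca_on_rate <= 0) stop("ca_on_rate must be > 0", call. = FALSE)
  l_i0 <- (1 / steady$l0) * cumprod(c(1, steady$kc / steady$ko))
  structure(
    list(steady = steady,
         opening_rate0 = as.numeric(opening_rate0),
         closing_rate0 = as.numeric(opening_rate0) / l_i0,
         charge_split = charge_split,
         ca_on_rate = ca_on_rate),
    class = "bk_kinetic"
  )
}

#' Rate generator of the ten-state model at fixed voltage and calcium
#'
#' Builds the 10x10 generator (rows = source states, order C0..C4, O0..O4;
#' rows sum to zero). Vertical rates scale as
#' `opening_rate0 * exp(charge_split * QFV/RT)` and
#' `closing_rate0 * exp(-(1 - charge_split) * QFV/RT)`; binding rates along
#' a tier are `(4 - i) * ca_on_rate * c` with unbinding rates set from the
#' dissociation constants with the same statistical factor.
#'
#' @param v Membrane potential, millivolts.
#' @param c Free calcium concentration, micromolar (>= 0).
#' @param p A `bk_kinetic` object.
#' @param constants A `ca_constants` object.
#' @return 10x10 generator matrix, rates in per-second.
#' @export
build_generator <- function(v, c, p, constants = physical_constants()) {
  stopifnot(inherits(p, "bk_kinetic"))
  if (c < 0) stop("free calcium concentration must be >= 0", call. = FALSE)
  s <- p$steady
  qfv <- s$gating_charge_q * constants$faraday_over_RT_mV * v
  al <- p$opening_rate0 * exp(p$charge_split * qfv)
  be <- p$closing_rate0 * exp(-(1 - p$charge_split) * qfv)
  G <- matrix(0, 10, 10,
              dimnames = list(.bk_state_names, .bk_state_names))
  for (i in 0:4) {
    G[1 + i, 6 + i] <- al[i + 1]
    G[6 + i, 1 + i] <- be[i + 1]
  }
  for (i in 0:3) {
    stat <- 4 - i
    G[1 + i, 2 + i] <- stat * p$ca_on_rate * c
    G[2 + i, 1 + i] <- stat * p$ca_on_rate * s$kc[i + 1]
    G[6 + i, 7 + i] <- stat * p$ca_on_rate * c
    G[7 + i, 6 + i] <- stat * p$ca_on_rate * s$ko[i + 1]
  }
  diag(G) <- -rowSums(G)
  G
}

.bk_state_names <- c(paste0("C", 0:4), paste0("O", 0:4))

#' Equilibrium occupancy of the generator at fixed voltage and calcium
#'
#' Stationary distribution (null vector of the transposed generator); its
#' open-tier mass reproduces [popen_steady()] — the kinetic and steady
#' parameterizations are one model.
#'
#' @inheritParams build_generator
#' @return Probability vector of length 10 (named C0..C4, O0..O4).
#' @export
gating_equilibrium <- function(v, c, p, constants = physical_constants()) {
  G <- build_generator(v, c, p, constants)
  ev <- eigen(t(G))
  k <- which.min(abs(ev$values))
  pi0 <- abs(Re(ev$vectors[, k]))
  stats::setNames(pi0 / sum(pi0), .bk_state_names)
}

#' Slowest relaxation time constant of the gating model
#'
#' Reciprocal of the smallest nonzero eigenvalue magnitude of the generator;
#' at the test potential with resting calcium this is the deactivation time
#' constant that limits current decay once calcium is cleared.
#'
#' @inheritParams build_generator
#' @return Time constant in milliseconds.
#' @export
gating_relaxation_tau <- function(v, c, p, constants = physical_constants()) {
  G <- build_generator(v, c, p, constants)
  lam <- sort(abs(Re(eigen(t(G), only.values = TRUE)$values)))
  1000 / lam[2]
}

#' Propagate the ten-state master equation along calcium/voltage time courses
#'
#' Integrates `dp/dt = G(v(t), c(t))^T p` on a common time grid (linear
#' interpolation between grid points) and reports the open probability
#' `O_tot / (C_tot + O_tot)` over time.
#'
#' @param times Time grid, milliseconds, strictly increasing.
#' @param c_of_t Free calcium (micromolar) at `times`, or a function of time.
#' @param v_of_t Membrane potential (millivolts) at `times`, or a function.
#' @param p A `bk_kinetic` object.
#' @param init Initial occupancy (length 10, sums to 1); defaults to the
#'   equilibrium at the initial voltage and calcium.
#' @param constants A `ca_constants` object.
#' @param rtol,atol Integrator tolerances.
#' @return A `popen_trace` object: `times` (ms), `values` (open
#'   probability), final `occupancy`.
#' @export
popen_dynamic <- function(times, c_of_t, v_of_t, p, init = NULL,
                          constants = physical_constants(),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(p, "bk_kinetic"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  cfun <- if (is.function(c_of_t)) c_of_t else
    stats::approxfun(times, c_of_t, rule = 2)
  vfun <- if (is.function(v_of_t)) v_of_t else
    stats::approxfun(times, v_of_t, rule = 2)
  if (is.null(init)) {
    init <- gating_equilibrium(vfun(times[1]), cfun(times[1]), p, constants)
  }
  if (abs(sum(init) - 1) > 1e-8 || any(init < -1e-12)) {
    stop("init must be a normalized occupancy vector", call. = FALSE)
  }
  rhs <- function(t, y, parms) {
    G <- build_generator(vfun(t), max(cfun(t), 0), p, constants)
    list(as.numeric(crossprod(G, y)) / 1000)       # rates per second -> ms
  }
  sol <- deSolve::lsoda(as.numeric(init), times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  occ <- sol[, -1, drop = FALSE]
  drift <- max(abs(rowSums(occ) - 1))
  if (drift > 1e-6) {
    stop("integration error: occupancy normalization drifted by ",
         signif(drift, 3), call. = FALSE)
  }
  structure(
    list(times = sol[, 1], values = rowSums(occ[, 6:10, drop = FALSE]),
         occupancy = occ[nrow(occ), ], protocol = NULL,
         tau_decay = NA_real_, fit_window = NULL),
    class = "popen_trace"
  )
}
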