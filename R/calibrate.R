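# Calibration of the gating model: the equilibrium structure is fitted to
# activation curves measured at several fixed calcium concentrations, and
# the transition rates are then fitted to responses to fast calcium switches
# at constant voltage with the equilibrium constants pinned. Both fits use
# bounded Levenberg-Marquardt least squares with seeded Latin-hypercube
# multistarts; the best start is returned and all starts are logged.
# Individual dissociation constants can be degenerate (a handful of curves
# cannot pin ten constants uniquely); calibration quality is judged on the
# predicted curves and the half-activation voltages they imply.

.steady_bounds <- list(
  lower = c(log_l0 = log(10), q = 0.5, log_k = rep(log(0.05), 8)),
  upper = c(log_l0 = log(1e6), q = 3.0, log_k = rep(log(200), 8))
)

.unpack_steady <- function(par) {
  bk_steady_params(l0 = exp(par[1]), gating_charge_q = par[2],
                   kc = exp(par[3:6]), ko = exp(par[7:10]))
}

.curves_as_list <- function(dataset) {
  if (is.data.frame(dataset)) {
    stopifnot(all(c("c_uM", "voltage_mV", "g_norm") %in% names(dataset)))
    lapply(split(dataset, dataset$c_uM), function(d) {
      list(c = d$c_uM[1], voltages = d$voltage_mV, g_norm = d$g_norm)
    })
  } else {
    dataset
  }
}

#' Calibrate the steady-state gating model to activation curves
#'
#' Bounded least squares over `{L(0), Q, K_C1..4, K_O1..4}` against
#' normalized activation curves recorded at two or more fixed calcium
#' concentrations, with seeded Latin-hypercube multistarts. Model curves are
#' normalized to their grid maximum exactly as the data convention.
#'
#' @param dataset Either a data frame with columns `c_uM`, `voltage_mV`,
#'   `g_norm`, or a list of `list(c=, voltages=, g_norm=)` curves.
#' @param n_starts Number of Latin-hypercube starting points.
#' @param seed Seed for the multistart draw.
#' @param constants A `ca_constants` object.
#' @return A list with `params` (a `bk_steady` object, or `NULL` on
#'   refusal), `refused` flag, and `report` holding per-curve RMSE, fitted
#'   half-activation voltages, the start log and the seed.
#' @export
calibrate_steady <- function(dataset, n_starts = 32, seed = 1,
                             constants = physical_constants()) {
  curves <- .curves_as_list(dataset)
  cs <- vapply(curves, function(x) x$c, numeric(1))
  if (length(unique(cs)) < 2L) {
    warning("activation curves at a single calcium concentration cannot ",
            "identify the calcium dependence; calibration refused")
    return(list(params = NULL, refused = TRUE,
                report = list(reason = "single-concentration dataset")))
  }

  resid <- function(par) {
    p <- tryCatch(.unpack_steady(par), error = function(e) NULL)
    if (is.null(p)) return(rep(1e3, sum(lengths(lapply(curves, `[[`,
                                                       "g_norm")))))
    unlist(lapply(curves, function(cv) {
      po <- popen_steady(cv$voltages, cv$c, p, constants)
      po / max(po) - cv$g_norm
    }), use.names = FALSE)
  }

  lo <- .steady_bounds$lower; up <- .steady_bounds$upper
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, length(lo))
  starts <- sweep(sweep(starts, 2, up - lo, "*"), 2, lo, "+")

  log <- vector("list", n_starts)
  best <- NULL; best_rss <- Inf
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid, lower = lo,
                         upper = up,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) { log[[s]] <- list(rss = NA_real_); next }
    rss <- sum(fit$fvec^2)
    log[[s]] <- list(rss = rss, par = fit$par)
    if (rss < best_rss) { best_rss <- rss; best <- fit }
  }
  if (is.null(best)) stop("all calibration starts failed", call. = FALSE)
  params <- .unpack_steady(best$par)

  per_curve <- lapply(curves, function(cv) {
    po <- popen_steady(cv$voltages, cv$c, params, constants)
    g <- po / max(po)
    bf <- fit_boltzmann(cv$voltages, g)
    list(c_uM = cv$c, rmse = sqrt(mean((g - cv$g_norm)^2)),
         vh_fitted = bf$vh, k_fitted = bf$k)
  })
  list(
    params = params, refused = FALSE,
    report = list(
      per_curve = per_curve,
      rmse_total = sqrt(best_rss / length(resid(best$par))),
      vh_by_c = data.frame(
        c_uM = vapply(per_curve, `[[`, numeric(1), "c_uM"),
        vh_mV = vapply(per_curve, `[[`, numeric(1), "vh_fitted")
      ),
      starts = log, seed = seed, n_starts = n_starts
    )
  )
}

# simulate the response to an instantaneous calcium switch at constant
# voltage by eigen-propagation of the (piecewise-constant) generator
.switch_response <- function(times, c_from, c_to, v_hold, p, constants) {
  p_init <- gating_equilibrium(v_hold, c_from, p, constants)
  G <- build_generator(v_hold, c_to, p, constants)
  ed <- eigen(t(G))
  a <- solve(ed$vectors, p_init)
  occ <- Re(ed$vectors %*% (a * exp(outer(ed$values, times / 1000))))
  colSums(occ[6:10, , drop = FALSE])
}

.kinetic_bounds <- list(
  lower = c(log_a0 = rep(log(1e-3), 5), split = 0.05, log_kon = log(1)),
  upper = c(log_a0 = rep(log(1e5), 5), split = 0.95, log_kon = log(1e4))
)

.unpack_kinetic <- function(par, steady) {
  bk_kinetic_params(steady, opening_rate0 = exp(par[1:5]),
                    charge_split = par[6], ca_on_rate = exp(par[7]))
}

#' Calibrate the kinetic gating model to calcium-switch responses
#'
#' Fits the rate-scale parameters (per-tier opening rates, charge split,
#' calcium on-rate) to open-probability responses to sub-millisecond
#' calcium switches at constant voltage, with all equilibrium constants
#' pinned to a previously calibrated steady-state set. Seeded multistart
#' bounded least squares.
#'
#' @param traces List of traces, each `list(times=, values=, c_from=,
#'   c_to=, v_hold=)` with times in ms.
#' @param steady A `bk_steady` object (pinned).
#' @param n_starts Number of Latin-hypercube starting points.
#' @param seed Seed for the multistart draw.
#' @param constants A `ca_constants` object.
#' @return A list with `params` (a `bk_kinetic` object), `report` (per-trace
#'   RMS, relative RMS, start log, identifiability flags, seed).
#' @export
calibrate_kinetic <- function(traces, steady, n_starts = 16, seed = 1,
                              constants = physical_constants()) {
  stopifnot(inherits(steady, "bk_steady"), length(traces) >= 2L)
  ca_info <- any(vapply(traces, function(x) x$c_from != x$c_to, logical(1)))
  resid <- function(par) {
    p <- tryCatch(.unpack_kinetic(par, steady), error = function(e) NULL)
    if (is.null(p)) return(rep(1e3, sum(vapply(traces, function(x)
      length(x$times), integer(1)))))
    unlist(lapply(traces, function(tr) {
      .switch_response(tr$times, tr$c_from, tr$c_to, tr$v_hold, p,
                       constants) - tr$values
    }), use.names = FALSE)
  }

  lo <- .kinetic_bounds$lower; up <- .kinetic_bounds$upper
  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, length(lo))
  starts <- sweep(sweep(starts, 2, up - lo, "*"), 2, lo, "+")

  log <- vector("list", n_starts)
  best <- NULL; best_rss <- Inf
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid, lower = lo,
                         upper = up,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(fit)) { log[[s]] <- list(rss = NA_real_); next }
    rss <- sum(fit$fvec^2)
    log[[s]] <- list(rss = rss, par = fit$par)
    if (rss < best_rss) { best_rss <- rss; best <- fit }
  }
  if (is.null(best)) stop("all calibration starts failed", call. = FALSE)
  params <- .unpack_kinetic(best$par, steady)

  per_trace <- lapply(traces, function(tr) {
    sim <- .switch_response(tr$times, tr$c_from, tr$c_to, tr$v_hold,
                            params, constants)
    rng <- diff(range(tr$values))
    list(rms = sqrt(mean((sim - tr$values)^2)),
         rms_rel = sqrt(mean((sim - tr$values)^2)) /
           (if (rng > 0) rng else 1))
  })
  rms_rel <- vapply(per_trace, `[[`, numeric(1), "rms_rel")
  list(
    params = params,
    report = list(
      per_trace = per_trace,
      rms_rel_max = max(rms_rel),
      large_residual = max(rms_rel) > 0.1,
      ca_on_rate_identifiable = ca_info,
      starts = log, seed = seed, n_starts = n_starts
    )
  )
}
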