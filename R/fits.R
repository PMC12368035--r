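# Trace and curve fitting: Boltzmann activation fits, mono-exponential decay
# fits, and immunogold density quantification.

#' Fit a Boltzmann function to a normalized activation curve
#'
#' Least-squares fit of `g = 1 / (1 + exp((vh - V) / k))` returning the
#' half-activation voltage, slope factor and residual. Data that a sigmoid
#' cannot describe better than a constant (flat or non-sigmoidal curves)
#' are reported with `failed = TRUE` rather than as a spurious fit.
#'
#' @param voltages Voltages, millivolts (>= 5 points spanning the
#'   transition).
#' @param g_norm Normalized conductance values.
#' @return A list with `vh` (mV), `k` (mV), `rmse`, `failed`.
#' @export
fit_boltzmann <- function(voltages, g_norm) {
  stopifnot(length(voltages) == length(g_norm))
  if (length(voltages) < 5L) {
    stop("need at least 5 points to fit a Boltzmann function", call. = FALSE)
  }
  ord <- order(voltages)
  v <- as.numeric(voltages[ord]); g <- as.numeric(g_norm[ord])
  rmse_const <- sqrt(mean((g - mean(g))^2))
  fail <- list(vh = NA_real_, k = NA_real_, rmse = rmse_const, failed = TRUE)
  if (diff(range(g)) < 1e-3) return(fail)

  # start values: crossing of 0.5 and a logit-slope estimate
  vh0 <- tryCatch(stats::approx(g, v, xout = 0.5, ties = "ordered")$y,
                  error = function(e) NA_real_)
  if (!is.finite(vh0)) vh0 <- v[which.min(abs(g - 0.5))]
  gi <- pmin(pmax(g, 1e-4), 1 - 1e-4)
  sl <- tryCatch(stats::coef(stats::lm(log(gi / (1 - gi)) ~ v))[2],
                 error = function(e) NA_real_)
  k0 <- if (is.finite(sl) && sl > 0) 1 / sl else diff(range(v)) / 6

  res_fn <- function(par) 1 / (1 + exp((par[1] - v) / par[2])) - g
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(vh0, k0), fn = res_fn,
                       lower = c(min(v) - 500, 1e-3),
                       upper = c(max(v) + 500, 1e4),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  rmse <- sqrt(mean(fit$fvec^2))
  if (rmse > 0.95 * rmse_const) return(fail)
  list(vh = unname(fit$par[1]), k = unname(fit$par[2]), rmse = rmse,
       failed = FALSE)
}

#' Fit a mono-exponential decay to a trace window
#'
#' Fits `a * exp(-(t - t0) / tau) + b` over a window, which by default
#' starts at the trace maximum (the post-pulse current peak) and runs to
#' the end of the record. Start values come from a log-linear regression on
#' the baseline-subtracted tail; non-decaying windows are flagged as fit
#' failures.
#'
#' @param times Times, milliseconds.
#' @param values Trace values (open probability or normalized current).
#' @param window Optional `c(start, end)` window in ms; default
#'   `c(t[which.max(values)], max(times))`.
#' @return A list with `tau` (ms), `amplitude`, `baseline`, `rmse`,
#'   `window`, `failed`.
#' @export
fit_monoexponential <- function(times, values, window = NULL) {
  stopifnot(length(times) == length(values))
  user_window <- !is.null(window)
  if (is.null(window)) {
    window <- c(times[which.max(values)], max(times))
  }
  sel <- times >= window[1] & times <= window[2]
  if (sum(sel) < 10L) {
    if (user_window) {
      stop("fit window must contain at least 10 samples", call. = FALSE)
    }
    # trace peaks at (or near) the record end: nothing decays
    return(list(tau = NA_real_, amplitude = NA_real_, baseline = NA_real_,
                rmse = NA_real_, window = window, failed = TRUE))
  }
  t <- times[sel] - window[1]
  y <- as.numeric(values[sel])
  fail <- list(tau = NA_real_, amplitude = NA_real_, baseline = NA_real_,
               rmse = NA_real_, window = window, failed = TRUE)

  n_tail <- max(5L, round(length(y) * 0.05))
  b0 <- mean(y[seq(length(y) - n_tail + 1, length(y))])
  if (y[1] - b0 <= 0) b0 <- min(y)
  a0 <- y[1] - b0
  if (a0 <= 0 || stats::coef(stats::lm(y ~ t))[2] >= 0) return(fail)
  # log-linear regression on the baseline-subtracted early decay
  pos <- which(y - b0 > 0.05 * a0)
  sl <- if (length(pos) >= 3) {
    stats::coef(stats::lm(log(y[pos] - b0) ~ t[pos]))[2]
  } else NA_real_
  tau0 <- if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3

  res_fn <- function(par) par[1] * exp(-t / par[2]) + par[3] - y
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, tau0, b0), fn = res_fn,
                       lower = c(0, 1e-6, -Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$par[1] <= 0) return(fail)
  list(tau = unname(fit$par[2]), amplitude = unname(fit$par[1]),
       baseline = unname(fit$par[3]), rmse = sqrt(mean(fit$fvec^2)),
       window = window, failed = FALSE)
}

#' Immunogold particle density estimate
#'
#' Surface density from a particle count over a measured replica area, the
#' quantification used for freeze-fracture immunogold labelling.
#'
#' @param count Number of gold particles (>= 0).
#' @param area Replica surface area, square micrometres (> 0).
#' @return A list of class `density_estimate` with `particle_count`,
#'   `area`, `density` (per square micrometre).
#' @export
em_density <- function(count, area) {
  if (any(area <= 0)) stop("area must be > 0", call. = FALSE)
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  structure(
    list(particle_count = count, area = area, density = count / area),
    class = "density_estimate"
  )
}

#' Aggregate immunogold densities across cells or structures
#'
#' @param counts,areas Paired particle counts and areas (one pair per
#'   cell/structure).
#' @return A list with per-item densities, their `mean`, `sem`, `n`, and the
#'   area-pooled estimate `pooled` (total count / total area).
#' @export
em_density_summary <- function(counts, areas) {
  stopifnot(length(counts) == length(areas))
  d <- em_density(counts, areas)$density
  list(densities = d, mean = mean(d),
       sem = stats::sd(d) / sqrt(length(d)), n = length(d),
       pooled = sum(counts) / sum(areas))
}
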