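# Synthetic calibration data. The raw recordings behind the calibration
# (activation curves at fixed pipette calcium, responses to sub-millisecond
# calcium switches, immunogold particle counts) are not redistributable, so
# the package generates statistically matched stand-ins from a documented
# truth parameter set. Every value in the truth set is a substitute chosen
# to satisfy the behavioural anchors of the experimental system, not a
# published constant; the anchors are checked by the test suite.

#' Default truth parameter set for the gating model
#'
#' Reference steady-state and kinetic BK parameter sets used to generate
#' synthetic calibration data and to drive the in-silico experiments. The
#' set is anchored to the behaviour of the experimental system rather than
#' to published constants (which are not redistributable here):
#' half-activation voltages decrease monotonically over pipette calcium
#' 0.1, 1, 10, 50 micromolar (about 178, 148, 10, -5 mV), and the slowest
#' gating relaxation at the +70 mV test potential with resting calcium —
#' the deactivation time constant that limits current decay once calcium is
#' cleared — is 8.4 ms, inside the 7-9 ms anchor band.
#'
#' @return A list of class `bk_truth` with `bk_steady`, `bk_kinetic` and
#'   `provenance` notes per value.
#' @export
default_truth <- function() {
  steady <- bk_steady_params(
    l0 = 4600, gating_charge_q = 1.2,
    kc = c(15, 10, 6, 4),
    ko = c(1.8, 1.1, 0.65, 0.45)
  )
  kinetic <- bk_kinetic_params(
    steady,
    opening_rate0 = 0.13464 * 8^(0:4),
    charge_split = 0.5,
    ca_on_rate = 2000
  )
  structure(
    list(
      bk_steady = steady,
      bk_kinetic = kinetic,
      provenance = c(
        l0 = "substitute; sets the resting-calcium half-activation near +178 mV",
        gating_charge_q = "substitute; effective BK gating charge ~1.2 e",
        kc = "substitute; closed-tier stepwise Kd, 4-15 uM range",
        ko = "substitute; open-tier stepwise Kd, ~8x tighter than closed",
        opening_rate0 = "substitute; 8x per-tier speed-up, base tuned so the slowest relaxation at (+70 mV, 0.1 uM) is 8.4 ms",
        charge_split = "substitute; symmetric charge split",
        ca_on_rate = "substitute; 2e9 /M/s per-site binding, fast enough that deactivation is gate-limited (mono-exponential)"
      )
    ),
    class = "bk_truth"
  )
}

#' Generate synthetic activation curves
#'
#' Steady-state activation curves of the truth model at the requested
#' calcium concentrations, with additive Gaussian noise on the normalized
#' conductance (clipped to \[0, 1.05\]). Regeneration with the same seed is
#' bit-identical.
#'
#' @param truth A `bk_truth` list (or a `bk_steady` object).
#' @param c_list Calcium concentrations, micromolar.
#' @param v_grid Voltage grid, millivolts.
#' @param noise_sigma Gaussian noise SD on the normalized conductance.
#' @param seed Seed for the noise draw.
#' @param constants A `ca_constants` object.
#' @return A data frame with columns `c_uM`, `voltage_mV`, `g_norm`, and
#'   attributes `noise_sigma`, `seed`.
#' @export
gen_activation_curves <- function(truth = default_truth(),
                                  c_list = c(0.1, 1, 10, 50),
                                  v_grid = seq(-80, 240, by = 10),
                                  noise_sigma = 0.02, seed = 1,
                                  constants = physical_constants()) {
  stopifnot(length(c_list) >= 1L, noise_sigma >= 0)
  p <- if (inherits(truth, "bk_steady")) truth else truth$bk_steady
  set.seed(seed)
  out <- do.call(rbind, lapply(c_list, function(cc) {
    po <- popen_steady(v_grid, cc, p, constants)
    g <- po / max(po)
    if (noise_sigma > 0) {
      g <- pmin(pmax(g + stats::rnorm(length(g), 0, noise_sigma), 0), 1.05)
    }
    data.frame(c_uM = cc, voltage_mV = v_grid, g_norm = g)
  }))
  attr(out, "noise_sigma") <- noise_sigma
  attr(out, "seed") <- seed
  out
}

#' Generate synthetic calcium-switch responses
#'
#' Open-probability responses of the truth kinetic model to instantaneous
#' calcium switches at constant holding potential, with optional additive
#' Gaussian noise. `c_from`, `c_to` and `v_hold` are recycled to a common
#' length, one trace per protocol.
#'
#' @param truth A `bk_truth` list (or a `bk_kinetic` object).
#' @param c_from,c_to Pre- and post-switch calcium, micromolar.
#' @param v_hold Holding potential, millivolts.
#' @param duration Trace duration, milliseconds.
#' @param dt Sample interval, milliseconds.
#' @param noise_sigma Gaussian noise SD on the open probability.
#' @param seed Seed for the noise draw.
#' @param constants A `ca_constants` object.
#' @return A list of traces `list(times, values, c_from, c_to, v_hold)`,
#'   directly consumable by [calibrate_kinetic()].
#' @export
gen_switch_responses <- function(truth = default_truth(),
                                 c_from = c(0.1, 10), c_to = c(10, 0.1),
                                 v_hold = 70, duration = 60, dt = 0.05,
                                 noise_sigma = 0, seed = 1,
                                 constants = physical_constants()) {
  p <- if (inherits(truth, "bk_kinetic")) truth else truth$bk_kinetic
  n <- max(length(c_from), length(c_to), length(v_hold))
  c_from <- rep_len(c_from, n); c_to <- rep_len(c_to, n)
  v_hold <- rep_len(v_hold, n)
  times <- seq(0, duration, by = dt)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vals <- .switch_response(times, c_from[i], c_to[i], v_hold[i], p,
                             constants)
    if (noise_sigma > 0) vals <- vals + stats::rnorm(length(vals), 0,
                                                     noise_sigma)
    list(times = times, values = vals, c_from = c_from[i],
         c_to = c_to[i], v_hold = v_hold[i])
  })
}

#' Generate synthetic immunogold replica counts
#'
#' Poisson particle counts over measured replica areas at a prescribed true
#' surface density, emulating freeze-fracture immunogold quantification.
#'
#' @param true_density True particle density, per square micrometre.
#' @param areas Replica areas, square micrometres.
#' @param seed Seed for the Poisson draw.
#' @return A data frame with columns `area_um2`, `count`, `density`, and
#'   attributes `true_density`, `seed`.
#' @export
gen_replica_counts <- function(true_density, areas, seed = 1) {
  if (true_density < 0) stop("true_density must be >= 0", call. = FALSE)
  set.seed(seed)
  counts <- stats::rpois(length(areas), true_density * areas)
  out <- data.frame(area_um2 = areas, count = counts,
                    density = counts / areas)
  attr(out, "true_density") <- true_density
  attr(out, "seed") <- seed
  out
}

#' Write a synthetic calibration dataset to a directory
#'
#' Writes activation curves, switch responses and replica counts as
#' tab-separated text files plus a JSON manifest holding the truth
#' parameters and seeds.
#'
#' @param dir Output directory (created if missing).
#' @param truth A `bk_truth` list.
#' @param seed Base seed; sub-seeds are derived per component.
#' @param noise_sigma Noise SD for the activation curves.
#' @return The manifest (invisibly).
#' @export
write_synthetic_dataset <- function(dir, truth = default_truth(), seed = 1,
                                    noise_sigma = 0.02) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  curves <- gen_activation_curves(truth, noise_sigma = noise_sigma,
                                  seed = seed)
  switches <- gen_switch_responses(truth, seed = seed + 1)
  counts <- gen_replica_counts(55, areas = rep(2, 10), seed = seed + 2)
  utils::write.table(curves, file.path(dir, "activation_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sw <- do.call(rbind, lapply(seq_along(switches), function(i) {
    s <- switches[[i]]
    data.frame(trace = i, time_ms = s$times, value = s$values,
               c_from = s$c_from, c_to = s$c_to, v_hold = s$v_hold)
  }))
  utils::write.table(sw, file.path(dir, "switch_responses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(counts, file.path(dir, "replica_counts.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    seed = seed, noise_sigma = noise_sigma,
    truth = list(
      l0 = truth$bk_steady$l0, gating_charge_q = truth$bk_steady$gating_charge_q,
      kc = truth$bk_steady$kc, ko = truth$bk_steady$ko,
      opening_rate0 = truth$bk_kinetic$opening_rate0,
      charge_split = truth$bk_kinetic$charge_split,
      ca_on_rate = truth$bk_kinetic$ca_on_rate
    ),
    files = c("activation_curves.tsv", "switch_responses.tsv",
              "replica_counts.tsv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
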