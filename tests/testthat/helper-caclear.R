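# shared fixtures, built in code
default_geom <- function() make_geometry(300, 0.3, 1.0)

# a short protocol for tests that only need the decay shape, not the full
# experimental record
short_protocol <- function(n_pulses = 1, record = 60) {
  influx_protocol(n_pulses = n_pulses, record_duration = record)
}

truth <- default_truth()

# interpolated time at which a concentration trace first falls below a level
crossing_time <- function(times, conc, level = 1, after = 0.8) {
  sel <- times > after
  tt <- times[sel]; cc <- conc[sel]
  i <- min(which(cc < level))
  if (!is.finite(i) || i == 1) return(NA_real_)
  tt[i - 1] + (tt[i] - tt[i - 1]) * (cc[i - 1] - level) / (cc[i - 1] - cc[i])
}

# detailed-balance check: product of rates around each 4-state loop
loop_imbalance <- function(G) {
  vapply(0:3, function(i) {
    fwd <- G[1 + i, 2 + i] * G[2 + i, 7 + i] * G[7 + i, 6 + i] *
      G[6 + i, 1 + i]
    bwd <- G[2 + i, 1 + i] * G[7 + i, 2 + i] * G[6 + i, 7 + i] *
      G[1 + i, 6 + i]
    fwd / bwd - 1
  }, numeric(1))
}
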