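# shared fixture builders: everything is generated in code at test time

hours_schedule <- c(0, 1, 4, 6, 8, 10, 12, 24, 36, 48, 60, 72)
days_schedule <- 0:14

# noiseless trajectory straight from a closed form
make_urea_traj <- function(params, strain = "test", times = hours_schedule) {
  trajectory(strain, "urea_gL", times, urea_model(times, params))
}

make_sigmoid_traj <- function(params, variable = "pH", strain = "test",
                              times = hours_schedule, unit = "hours") {
  trajectory(strain, variable, times, sigmoid_model(times, params),
             time_unit = unit)
}

make_ca_traj <- function(params, strain = "test", times = days_schedule) {
  trajectory(strain, "calcium_mgL", times, ca_model(times, params),
             time_unit = "days")
}

# spreadsheet-style brute-force standard score, independent of the package
# implementation: explicit loops, no matrix algebra
brute_force_ss <- function(raw, weights) {
  n <- nrow(raw); p <- ncol(raw)
  ss <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(p)) {
      lo <- min(raw[, j]); hi <- max(raw[, j])
      xbar <- if (hi > lo) (raw[i, j] - lo) / (hi - lo) else 0
      acc <- acc + weights[j] * xbar
    }
    ss[i] <- acc
  }
  ss
}

rel_err <- function(est, true) {
  ifelse(true == 0, abs(est - true), abs(est - true) / abs(true))
}
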