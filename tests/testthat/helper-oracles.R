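# Independent oracles used across the suite.

# At alpha = 1 the implicit crossover equation is the quadratic
# x (2 + x) = 2 n, so x = -1 + sqrt(1 + 2 n) in closed form.
closed_form_x_alpha1 <- function(n) -1 + sqrt(1 + 2 * n)

# Brute-force time-averaged MSD: double loop over lags and start points.
brute_force_tamsd <- function(traj, step_lag) {
  n <- nrow(traj)
  acc <- 0
  cnt <- 0
  for (i in seq_len(n - step_lag)) {
    acc <- acc + (traj$x[i + step_lag] - traj$x[i])^2 +
      (traj$y[i + step_lag] - traj$y[i])^2
    cnt <- cnt + 1
  }
  acc / cnt
}

rel_err <- function(got, want) abs(got / want - 1)

# log-log slope of an MSD series over its last points
tail_loglog_slope <- function(series, n_tail = nrow(series)) {
  idx <- seq(nrow(series) - n_tail + 1, nrow(series))
  stats::coef(stats::lm(log(msd) ~ log(time), data = series[idx, ]))[[2]]
}
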