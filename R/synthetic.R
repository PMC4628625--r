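#' Generate a model-consistent noisy MSD series
#'
#' Forward-simulates MSD observations: the crossover model evaluated at the
#' requested times, multiplied by independent lognormal noise with mean 1
#' and the requested coefficient of variation. Multiplicative lognormal
#' noise (rather than additive Gaussian) keeps every simulated MSD
#' positive at any noise level, which the MSD invariants require.
#' Seed-deterministic; the caller's RNG state is left untouched.
#'
#' @param params A [walk_params()] object.
#' @param times Strictly positive, strictly increasing observation times.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0;
#'   0 returns the exact model values).
#' @param seed Integer seed.
#' @param dimensionality 1, 2 or 3; default 2.
#' @return An [as_msd_series()] tibble with columns `time`, `msd`.
#' @examples
#' p <- walk_params(0.0559, 3.77e-4, alpha = 0.862)
#' generate_msd_series(p, c(0.035, 0.07, 0.105, 0.14), cv = 0.02, seed = 1)
#' @export
generate_msd_series <- function(params, times, cv = 0, seed = 1L,
                                dimensionality = 2) {
  stopifnot(inherits(params, "walk_params"), is.numeric(times))
  if (any(!is.finite(times) | times <= 0)) {
    stop("`times` must be finite and > 0.", call. = FALSE)
  }
  if (!is.numeric(cv) || length(cv) != 1L || !is.finite(cv) || cv < 0) {
    stop("`cv` must be a single non-negative number.", call. = FALSE)
  }
  truth <- msd(times, params, dimensionality)
  if (cv == 0) {
    eps <- rep(1, length(times))
  } else {
    sdlog <- sqrt(log1p(cv^2))
    eps <- withr::with_seed(seed,
      stats::rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  as_msd_series(tibble::tibble(time = times, msd = truth * eps),
                dimensionality = dimensionality)
}

#' Generate a stand-in 2D trajectory with equal-length steps
#'
#' A fixture generator, not part of the model: the crossover theory is a
#' statement about MSD, and defines no microscopic update rule. This walk
#' takes steps of exactly the mean free path `lambda`, one per step time
#' `tau`, and couples successive headings through a simple mixture tuned by
#' `alpha`: with probability `|alpha - 1|` the new heading repeats
#' (`alpha > 1`) or reverses (`alpha < 1`) the previous one, otherwise it
#' is drawn uniformly. The two anchor cases are exact — `alpha = 2` gives a
#' perfectly collinear (ballistic) path and `alpha = 1` an uncorrelated
#' random walk — while intermediate values merely push the empirical MSD
#' exponent toward `alpha` at moderate lags. Use it to exercise
#' trajectory-processing code, never as a reference realization of the
#' model.
#'
#' The particle moves along each segment at the constant speed
#' `lambda / tau`, so with `samples_per_step > 1` the positions are sampled
#' inside segments too; lags shorter than `tau` then resolve the ballistic
#' regime, which is what the two-point mean-free-path estimator needs.
#'
#' @param params A [walk_params()] object; `lambda`, `tau` and `alpha` are
#'   used.
#' @param n_steps Number of steps (>= 2).
#' @param seed Integer seed.
#' @param samples_per_step Position samples per segment (integer >= 1);
#'   sampling interval `tau / samples_per_step`.
#' @return A tibble of class `trajectory_table` with columns `time`, `x`,
#'   `y` (`n_steps * samples_per_step + 1` rows, starting at the origin).
#' @export
generate_trajectory <- function(params, n_steps, seed = 1L,
                                samples_per_step = 1L) {
  stopifnot(inherits(params, "walk_params"))
  if (!is.numeric(n_steps) || n_steps < 2) {
    stop("`n_steps` must be at least 2.", call. = FALSE)
  }
  if (!is.numeric(samples_per_step) || samples_per_step < 1) {
    stop("`samples_per_step` must be a positive integer.", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  spp <- as.integer(samples_per_step)
  a <- params$alpha
  headings <- withr::with_seed(seed, {
    theta <- numeric(n_steps)
    theta[1L] <- stats::runif(1, 0, 2 * pi)
    p_keep <- abs(a - 1)
    turn <- if (a >= 1) 0 else pi
    if (n_steps > 1L) {
      u <- stats::runif(n_steps - 1L)
      fresh <- stats::runif(n_steps - 1L, 0, 2 * pi)
      for (i in 2:n_steps) {
        theta[i] <- if (u[i - 1L] < p_keep) theta[i - 1L] + turn else fresh[i - 1L]
      }
    }
    theta
  })
  sub <- params$lambda / spp
  x <- c(0, cumsum(rep(sub * cos(headings), each = spp)))
  y <- c(0, cumsum(rep(sub * sin(headings), each = spp)))
  out <- tibble::tibble(time = params$tau / spp * (0:(n_steps * spp)),
                        x = x, y = y)
  class(out) <- c("trajectory_table", class(out))
  out
}

#' Time-averaged MSD of a trajectory
#'
#' The standard single-trajectory estimator: for each lag `Delta`,
#' `TA-MSD(Delta)` is the mean of `|r(t + Delta) - r(t)|^2` over all start
#' times on the sampling grid. Lags must be multiples of the (uniform)
#' sampling interval and shorter than the trajectory span.
#'
#' @param traj A data frame with columns `time`, `x`, `y` sampled at a
#'   uniform interval (e.g. from [generate_trajectory()]).
#' @param lags Lag times, each a multiple of the sampling interval.
#' @return An [as_msd_series()] tibble (dimensionality 2) with one row per
#'   lag.
#' @examples
#' tr <- generate_trajectory(walk_params(1, 1), n_steps = 100, seed = 2)
#' msd_from_trajectory(tr, lags = c(1, 2, 5))
#' @export
msd_from_trajectory <- function(traj, lags) {
  if (!is.data.frame(traj) || !all(c("time", "x", "y") %in% names(traj))) {
    stop("`traj` must be a data frame with columns time, x, y.", call. = FALSE)
  }
  n <- nrow(traj)
  if (n < 2L) stop("trajectory needs at least two samples.", call. = FALSE)
  dt <- diff(traj$time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * dt[1L]) {
    stop("trajectory must be sampled at a uniform, strictly increasing ",
         "interval.", call. = FALSE)
  }
  dt <- dt[1L]
  steps <- lags / dt
  if (any(abs(steps - round(steps)) > 1e-8)) {
    stop("each lag must be a multiple of the sampling interval ",
         format(dt), ".", call. = FALSE)
  }
  steps <- as.integer(round(steps))
  span <- traj$time[n] - traj$time[1L]
  if (any(lags <= 0) || any(lags >= span + 1e-12 * span)) {
    bad <- lags[lags <= 0 | lags > span]
    stop("lags must be positive and no longer than the trajectory span (",
         format(span), "); offending lag(s): ",
         paste(format(bad), collapse = ", "), ".", call. = FALSE)
  }
  ta_msd <- vapply(steps, function(m) {
    i <- seq_len(n - m)
    mean((traj$x[i + m] - traj$x[i])^2 + (traj$y[i + m] - traj$y[i])^2)
  }, numeric(1))
  as_msd_series(tibble::tibble(time = steps * dt, msd = ta_msd),
                dimensionality = 2)
}
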