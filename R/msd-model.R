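#' Normalized mean-square displacement from the implicit crossover equation
#'
#' The model's central result: writing `x = sqrt(<r^2>) / lambda` and
#' `n = t / tau` (the number of Brownian steps), the MSD at any time
#' satisfies the implicit equation
#'
#'     x * (k + x)^((2 - alpha) / alpha) = k^((2 - alpha) / alpha) * n
#'
#' whose unique non-negative root interpolates between the ballistic law
#' `x = n` at short times and the anomalous power law
#' `x^2 = k^(2 - alpha) * n^alpha` at long times. `msd_normalized()`
#' returns `y = x^2 = <r^2> / lambda^2`.
#'
#' The left-hand side is strictly increasing in `x`, so the root is unique
#' and bracketed by the ballistic bound `x <= n` (displacement cannot
#' exceed contour length) and the power-law bound
#' `x <= k^((2-alpha)/2) n^(alpha/2)`. The solver works on `log x`, where
#' the equation is well conditioned at both extremes, and converges to a
#' relative tolerance near machine precision (see the package vignette).
#'
#' @param t_over_tau Time in units of the Brownian step time; `>= 0`.
#'   Vectorized.
#' @param alpha Anomalous diffusion exponent in `[0.05, 2]`. `alpha = 2`
#'   is evaluated on the exact ballistic branch (`y = n^2`).
#' @param k Crossover constant, default 2.
#' @return `<r^2> / lambda^2`, same length as `t_over_tau`.
#' @examples
#' msd_normalized(4, alpha = 1)   # exactly 4: x solves x (2 + x) = 8
#' msd_normalized(10, alpha = 2)  # 100, ballistic
#' @export
msd_normalized <- function(t_over_tau, alpha, k = 2) {
  check_alpha(alpha)
  if (!is.finite(k) || k <= 0) stop("`k` must be positive.", call. = FALSE)
  if (any(!is.finite(t_over_tau) | t_over_tau < 0)) {
    stop("`t_over_tau` must be finite and >= 0.", call. = FALSE)
  }
  vapply(t_over_tau, solve_msd_root, numeric(1), alpha = alpha, k = k)^2
}

# Root x of x (k + x)^e = k^e n with e = (2 - alpha)/alpha, solved on log x.
# Bracket: x <= n (ballistic bound) and x <= k^((2-alpha)/2) n^(alpha/2)
# (power-law bound) give the upper end; pushing the upper bound back through
# the equation gives a guaranteed lower end.
solve_msd_root <- function(n, alpha, k) {
  if (n == 0) return(0)
  if (alpha == 2) return(n)          # exponent (2 - alpha)/alpha is 0
  e <- (2 - alpha) / alpha
  x_up <- min(n, k^((2 - alpha) / 2) * n^(alpha / 2))
  x_lo <- n * (k / (k + x_up))^e     # f(x_lo) <= 0 since x_lo <= x <= x_up
  g <- function(z) {
    x <- exp(z)
    z + e * log1p(x / k) - log(n)    # log of both sides, minus
  }
  lo <- log(x_lo); up <- log(x_up)
  # deep in an asymptotic regime the two bounds already agree to within
  # the target tolerance; no root search is needed (or possible)
  if (up - lo < 1e-12) return(exp((lo + up) / 2))
  # guard against rounding putting the root on a bracket end
  if (g(lo) > 0) return(x_lo)
  if (g(up) < 0) return(x_up)
  root <- stats::uniroot(g, c(lo, up), tol = 1e-14, maxiter = 200L)
  exp(root$root)
}

#' Mean-square displacement of the crossover model
#'
#' Dimensional MSD at time `t` for a walk with parameters `params`. The
#' canonical solution is two-dimensional (the plane of a supported lipid
#' bilayer); other dimensionalities rescale it by isotropy:
#' `<R^2>_3D = (3/2) <r^2>_2D` and `<x^2>_1D = (1/2) <r^2>_2D`, matching
#' the `2 Gamma t^alpha` (1D) vs `4 Gamma t^alpha` (2D) conventions.
#'
#' @param t Time(s), `>= 0`. Vectorized.
#' @param params A [walk_params()] object.
#' @param dimensionality 1, 2 or 3. Default 2.
#' @return MSD in length^2 units, same length as `t`.
#' @examples
#' p <- walk_params(lambda = 1, tau = 1, alpha = 1)
#' msd(4, p)        # 4
#' msd(4, p, 3)     # 6
#' @export
msd <- function(t, params, dimensionality = 2) {
  stopifnot(inherits(params, "walk_params"))
  y2d <- msd_normalized(t / params$tau, params$alpha, params$k) * params$lambda^2
  dim_factor(dimensionality) * y2d
}

dim_factor <- function(dimensionality) {
  if (!dimensionality %in% c(1, 2, 3)) {
    stop("`dimensionality` must be 1, 2 or 3.", call. = FALSE)
  }
  c(0.5, 1, 1.5)[dimensionality]
}

#' Short- and long-time asymptotes of the crossover model
#'
#' `msd_ballistic()` is the short-time limit `<r^2> = (lambda t / tau)^2 =
#' (v0 t)^2`, independent of `k` and `alpha`. `msd_longtime()` is the
#' long-time anomalous law `<r^2> = k^(2 - alpha) lambda^2 (t/tau)^alpha`,
#' which at the canonical `k = 2` equals `4 Gamma t^alpha` with `Gamma`
#' from [transport_coefficient()].
#'
#' @inheritParams msd
#' @return MSD in length^2 units (2D).
#' @export
msd_ballistic <- function(t, params) {
  stopifnot(inherits(params, "walk_params"))
  if (any(!is.finite(t) | t < 0)) stop("`t` must be finite and >= 0.", call. = FALSE)
  (params$lambda * t / params$tau)^2
}

#' @rdname msd_ballistic
#' @export
msd_longtime <- function(t, params) {
  stopifnot(inherits(params, "walk_params"))
  if (any(!is.finite(t) | t < 0)) stop("`t` must be finite and >= 0.", call. = FALSE)
  params$k^(2 - params$alpha) * params$lambda^2 * (t / params$tau)^params$alpha
}

#' Degree of advancement of anomalous diffusion
#'
#' The 2D MSD normalized by its long-time law, `<r^2> / (4 Gamma t^alpha)`.
#' It runs from 0 (ballistic regime, for `alpha < 2`) to 1 (fully developed
#' anomalous diffusion) and measures how far along the crossover the motion
#' is at time `t`; the rise spans roughly three decades of `t / tau`. The
#' model solution obeys the exact identity
#'
#'     (sqrt(<r^2>) / (v0 t))^(alpha / (2 - alpha)) +
#'       (<r^2> / (4 Gamma t^alpha))^(1 / (2 - alpha)) = 1
#'
#' which splits the motion into its ballistic and diffusive shares.
#' Defined for the canonical `k = 2`.
#'
#' @inheritParams msd
#' @return Values in `(0, 1)` (exactly 1 in the ballistic `alpha = 2` branch).
#' @export
normalized_msd <- function(t, params) {
  stopifnot(inherits(params, "walk_params"))
  if (any(!is.finite(t) | t <= 0)) stop("`t` must be finite and > 0.", call. = FALSE)
  gam <- transport_coefficient(params)
  msd(t, params, dimensionality = 2) / (4 * gam * t^params$alpha)
}

#' Tabulate the model MSD and its asymptotes on a time grid
#'
#' Convenience forward-model table used by plots and the `predict` CLI
#' subcommand: for each time it reports the model MSD, the ballistic and
#' long-time asymptotes, the normalized MSD `<r^2> / (4 Gamma t^alpha)`,
#' and the universal coordinate `Gamma / D * tau^(alpha - 1)` (constant,
#' `2^(1 - alpha)`).
#'
#' @param params A [walk_params()] object.
#' @param times Strictly positive time points; default a log-spaced grid
#'   of `n` points spanning `t / tau` from 1e-3 to 1e6.
#' @param n Number of grid points when `times` is not given.
#' @param dimensionality 1, 2 or 3 for the `msd` column (asymptotes and
#'   normalized columns stay in the canonical 2D convention).
#' @return A tibble with columns `time`, `t_over_tau`, `msd`,
#'   `msd_ballistic`, `msd_longtime`, `normalized_msd`, `universal`.
#' @examples
#' predict_msd(walk_params(1, 1, alpha = 0.8), n = 5)
#' @export
predict_msd <- function(params, times = NULL, n = 200, dimensionality = 2) {
  stopifnot(inherits(params, "walk_params"))
  if (is.null(times)) {
    times <- params$tau * 10^seq(-3, 6, length.out = n)
  }
  if (any(!is.finite(times) | times <= 0)) {
    stop("`times` must be finite and > 0.", call. = FALSE)
  }
  tibble::tibble(
    time = times,
    t_over_tau = times / params$tau,
    msd = msd(times, params, dimensionality),
    msd_ballistic = msd_ballistic(times, params),
    msd_longtime = msd_longtime(times, params),
    normalized_msd = normalized_msd(times, params),
    universal = gamma_over_D(params$tau, params$alpha) * params$tau^(params$alpha - 1)
  )
}
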