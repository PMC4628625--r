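#' Microscopic parameters of the fractal random walk
#'
#' `walk_params()` bundles the four quantities that fully determine the
#' crossover MSD model: the two-dimensional mean free path `lambda` (the
#' length of one elementary straight segment of the trajectory), the
#' Brownian step time `tau` (the duration of one segment), the anomalous
#' diffusion exponent `alpha` (MSD grows as `t^alpha` at long times), and
#' the crossover constant `k` that sets where the scale-dependent fractal
#' dimension turns over. `k = 2` is the canonical choice: it is the value
#' for which the long-time law reduces to the familiar `<r^2> = 4 D t` at
#' `alpha = 1`, so all derived coefficients (`diffusion_coefficient()`,
#' `transport_coefficient()`, `gamma_over_D()`) assume it.
#'
#' The trajectory fractal dimension is `D_w = 2 / alpha`: 1 for ballistic
#' motion, 2 for Brownian motion, above 2 for sub-diffusion.
#'
#' Units are the caller's responsibility and need only be self-consistent;
#' micrometres and seconds are the conventional pairing for membrane
#' single-particle tracking.
#'
#' @param lambda Mean free path (length > 0), in 2D.
#' @param tau Brownian step time (> 0).
#' @param alpha Anomalous diffusion exponent, in `[0.05, 2]`. Values below
#'   0.05 are rejected as numerically meaningless; `alpha = 2` is the exact
#'   ballistic branch.
#' @param k Crossover constant (> 0). Default 2; see Details.
#'
#' @return An object of class `walk_params`: a named list with elements
#'   `lambda`, `tau`, `alpha`, `k`.
#' @examples
#' p <- walk_params(lambda = 0.0559, tau = 3.77e-4, alpha = 0.862)
#' diffusion_coefficient(p)
#' @export
walk_params <- function(lambda, tau, alpha = 1, k = 2) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            is.numeric(tau), length(tau) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(k), length(k) == 1L)
  if (!is.finite(lambda) || lambda <= 0) {
    stop("`lambda` (mean free path) must be a positive finite number.", call. = FALSE)
  }
  if (!is.finite(tau) || tau <= 0) {
    stop("`tau` (Brownian step time) must be a positive finite number.", call. = FALSE)
  }
  check_alpha(alpha)
  if (!is.finite(k) || k <= 0) {
    stop("`k` (crossover constant) must be a positive finite number.", call. = FALSE)
  }
  structure(
    list(lambda = as.numeric(lambda), tau = as.numeric(tau),
         alpha = as.numeric(alpha), k = as.numeric(k)),
    class = "walk_params"
  )
}

# alpha validity shared by the fitting routines (which scan alpha without
# constructing a walk_params each time)
check_alpha <- function(alpha) {
  if (!is.finite(alpha) || alpha < 0.05 || alpha > 2) {
    stop("`alpha` must lie in [0.05, 2]; got ", format(alpha), ".", call. = FALSE)
  }
  invisible(alpha)
}

#' @export
print.walk_params <- function(x, ...) {
  cat("<walk_params>\n")
  cat(sprintf("  lambda (mean free path): %g\n", x$lambda))
  cat(sprintf("  tau (step time):         %g\n", x$tau))
  cat(sprintf("  alpha (exponent):        %g  (D_w = %g)\n", x$alpha, 2 / x$alpha))
  cat(sprintf("  k (crossover constant):  %g\n", x$k))
  cat(sprintf("  derived: D = %g, Gamma = %g, v0 = %g\n",
              diffusion_coefficient(x), transport_coefficient(x), mean_velocity(x)))
  invisible(x)
}

#' Diffusion coefficient of the unobstructed walk
#'
#' `D = lambda^2 / (2 tau)`, the ordinary (`alpha = 1`) diffusion
#' coefficient implied by the microscopic step. Units length^2/time.
#'
#' @param params A [walk_params()] object.
#' @return Scalar diffusion coefficient.
#' @examples
#' diffusion_coefficient(walk_params(0.0559, 3.77e-4)) # ~4.15 um^2/s
#' @export
diffusion_coefficient <- function(params) {
  stopifnot(inherits(params, "walk_params"))
  params$lambda^2 / (2 * params$tau)
}

#' Transport coefficient of anomalous diffusion
#'
#' The generalized diffusion prefactor `Gamma` in the long-time law
#' `<r^2> = 4 Gamma t^alpha` (2D): `Gamma = 2^(-alpha) lambda^2 / tau^alpha`.
#' Units length^2/time^alpha. At `alpha = 1` it equals the diffusion
#' coefficient; at `alpha = 2` it is `v0^2 / 4`.
#'
#' @inheritParams diffusion_coefficient
#' @return Scalar transport coefficient.
#' @export
transport_coefficient <- function(params) {
  stopifnot(inherits(params, "walk_params"))
  2^(-params$alpha) * params$lambda^2 / params$tau^params$alpha
}

#' Ratio of transport to diffusion coefficient
#'
#' `Gamma / D = (2 tau)^(1 - alpha)`: the transport coefficient normalized
#' by the diffusion constant depends only on the step time and the
#' exponent. Multiplied by `tau^(alpha - 1)` it collapses to the universal
#' curve `2^(1 - alpha)`, on which systems with different characteristic
#' times can be compared.
#'
#' @param tau Brownian step time (> 0).
#' @param alpha Anomalous diffusion exponent.
#' @return `(2 tau)^(1 - alpha)`, units time^(1 - alpha).
#' @examples
#' 4.15 * gamma_over_D(3.77e-4, 0.573) # ~0.193, a fitted Gamma
#' @export
gamma_over_D <- function(tau, alpha) {
  stopifnot(is.numeric(tau), all(tau > 0), is.numeric(alpha))
  (2 * tau)^(1 - alpha)
}

#' Mean velocity of the particle along its trajectory
#'
#' Three equivalent routes to the 2D mean velocity `v0`, used according to
#' which quantities are known:
#' * from the microscopic step, `v0 = lambda / tau` (pass `params`);
#' * from ordinary-diffusion calibration, `v0 = 2 D / lambda`
#'   (pass `D` and `lambda`);
#' * from the anomalous pair, `v0 = 2 sqrt(D) (Gamma/D)^(1 / (2 (alpha - 1)))`
#'   (pass `D`, `gamma` and `alpha`; singular at `alpha = 1`, where the
#'   `D`/`lambda` form must be used instead).
#'
#' The three agree exactly when their arguments are mutually consistent
#' through `D = lambda^2/(2 tau)` and `Gamma = 2^(-alpha) lambda^2 / tau^alpha`.
#'
#' @param params A [walk_params()] object (first form).
#' @param D Diffusion coefficient (second and third forms).
#' @param lambda Mean free path (second form).
#' @param gamma Transport coefficient (third form).
#' @param alpha Anomalous diffusion exponent (third form; must differ from 1).
#' @return Scalar mean velocity, length/time.
#' @examples
#' mean_velocity(D = 4.15, lambda = 0.0559)            # ~148 um/s
#' mean_velocity(D = 4.15, gamma = 1.55, alpha = 0.86) # ~137 um/s
#' @export
mean_velocity <- function(params = NULL, D = NULL, lambda = NULL,
                          gamma = NULL, alpha = NULL) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "walk_params"))
    return(params$lambda / params$tau)
  }
  if (!is.null(D) && !is.null(lambda)) {
    stopifnot(D > 0, lambda > 0)
    return(2 * D / lambda)
  }
  if (!is.null(D) && !is.null(gamma) && !is.null(alpha)) {
    stopifnot(D > 0, gamma > 0)
    if (abs(alpha - 1) < 1e-12) {
      stop("mean velocity from (D, gamma, alpha) is singular at alpha = 1; ",
           "use the (D, lambda) form.", call. = FALSE)
    }
    return(2 * sqrt(D) * (gamma / D)^(1 / (2 * (alpha - 1))))
  }
  stop("supply `params`, or (`D`, `lambda`), or (`D`, `gamma`, `alpha`).",
       call. = FALSE)
}

#' Serialize walk parameters to and from JSON
#'
#' A flat JSON object `{"lambda": ..., "tau": ..., "alpha": ..., "k": ...}`.
#' Units are whatever the caller used (conventionally micrometres/seconds).
#'
#' @param params A [walk_params()] object.
#' @param path File path; for `walk_params_to_json()`, `NULL` returns the
#'   JSON string instead of writing.
#' @return `walk_params_to_json()`: the path (invisibly) or a JSON string.
#'   `walk_params_from_json()`: a [walk_params()] object.
#' @export
walk_params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "walk_params"))
  json <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' @rdname walk_params_to_json
#' @export
walk_params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  required <- c("lambda", "tau", "alpha")
  if (!all(required %in% names(x))) {
    stop("JSON walk parameters need fields: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  walk_params(lambda = x$lambda, tau = x$tau, alpha = x$alpha,
              k = if (is.null(x$k)) 2 else x$k)
}
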