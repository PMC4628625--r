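#' Scale-dependent fractal dimension profile of a trajectory
#'
#' A trajectory observed on a scale much shorter than the mean free path
#' looks like a straight line (fractal dimension 1); on large scales it
#' attains its asymptotic dimension `dw` (2 for Brownian motion, above 2
#' for sub-diffusion, below 2 for super-diffusion). The profile
#' interpolates between the two with a single crossover scale `k * Lambda`,
#' where `Lambda` is the three-dimensional mean free path,
#' `Lambda = sqrt(3/2) * lambda`.
#'
#' @param dw Asymptotic trajectory fractal dimension (>= 1).
#' @param Lambda Three-dimensional mean free path (> 0).
#' @param k Crossover constant (> 0), default 2.
#' @return An object of class `scale_profile`.
#' @seealso [scale_dependent_dimension()], [contour_ratio()]
#' @export
scale_profile <- function(dw, Lambda, k = 2) {
  stopifnot(is.numeric(dw), length(dw) == 1L,
            is.numeric(Lambda), length(Lambda) == 1L,
            is.numeric(k), length(k) == 1L)
  if (!is.finite(dw) || dw < 1) {
    stop("`dw` (asymptotic fractal dimension) must be >= 1.", call. = FALSE)
  }
  if (!is.finite(Lambda) || Lambda <= 0) {
    stop("`Lambda` (mean free path) must be positive.", call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) {
    stop("`k` must be positive.", call. = FALSE)
  }
  structure(list(dw = dw, Lambda = Lambda, k = k), class = "scale_profile")
}

#' Fractal dimension of the trajectory at a given observation scale
#'
#' Evaluates `D_w(s) = D_w - (D_w - 1) / (1 + s / (k * Lambda))`: equal to 1
#' at `s = 0` (ballistic on the smallest scales), rising monotonically to
#' the asymptotic `D_w` as the observation scale grows past the crossover
#' scale `k * Lambda`.
#'
#' @param s Observation scale(s), length units; `s >= 0`. Vectorized.
#' @param profile A [scale_profile()].
#' @return Numeric vector of fractal dimensions, in `[1, dw]`.
#' @examples
#' pr <- scale_profile(dw = 2, Lambda = 1)
#' scale_dependent_dimension(c(0, 2, 1e6), pr)
#' @export
scale_dependent_dimension <- function(s, profile) {
  stopifnot(inherits(profile, "scale_profile"), is.numeric(s))
  if (any(!is.finite(s) | s < 0)) {
    stop("observation scale `s` must be finite and >= 0.", call. = FALSE)
  }
  profile$dw - (profile$dw - 1) / (1 + s / (profile$k * profile$Lambda))
}

#' Displacement-to-contour-length ratio of a fractal trajectory
#'
#' Integrating the fractal length relation
#' `d log L / d log s = 1 - D_w(s)` over the scale-dependent dimension
#' profile gives the closed form
#' `r / L(0) = (1 + r / (k * Lambda))^-(D_w - 1)`,
#' the net displacement `r` as a fraction of the trajectory contour length
#' `L(0) = v0 * t`. It is 1 for a ballistic path (`dw = 1`, displacement
#' equals contour) and decays toward 0 for large `r` when `dw > 1`.
#'
#' @param r Net displacement(s), `r >= 0`. Vectorized.
#' @param params A [walk_params()] object; its 2D mean free path is
#'   converted internally to the 3D one, `Lambda = sqrt(3/2) * lambda`.
#' @param dw Trajectory fractal dimension (>= 1); defaults to the value
#'   `2 / alpha` implied by `params`.
#' @return Numeric vector in `(0, 1]`.
#' @export
contour_ratio <- function(r, params, dw = 2 / params$alpha) {
  stopifnot(inherits(params, "walk_params"), is.numeric(r))
  if (any(!is.finite(r) | r < 0)) {
    stop("displacement `r` must be finite and >= 0.", call. = FALSE)
  }
  if (dw < 1) stop("`dw` must be >= 1.", call. = FALSE)
  Lambda <- sqrt(3 / 2) * params$lambda
  (1 + r / (params$k * Lambda))^(-(dw - 1))
}
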