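#' Plot a fitted crossover model against its data
#'
#' Log-log plot of the observed MSD points with the fitted model curve and
#' its two asymptotes: the ballistic short-time law `(v0 t)^2` and the
#' anomalous long-time law `4 Gamma t^alpha`.
#'
#' @param object An `msd_fit` object (with its data attached).
#' @param n_curve Number of points along the model curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msd_fit <- function(object, n_curve = 200, ...) {
  series <- object$data
  if (is.null(series)) stop("fit carries no data to plot.", call. = FALSE)
  params <- walk_params(object$lambda, object$tau, object$alpha)
  tr <- range(series$time)
  times <- 10^seq(log10(tr[1]) - 1.5, log10(tr[2]) + 1.5, length.out = n_curve)
  curves <- predict_msd(params, times = times)
  long <- tibble::tibble(
    time = rep(curves$time, 3),
    msd = c(curves$msd, curves$msd_ballistic, curves$msd_longtime),
    which = rep(c("model", "ballistic asymptote", "long-time asymptote"),
                each = nrow(curves))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$msd)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$which,
                                    colour = .data$which)) +
    ggplot2::geom_point(data = tibble::tibble(time = series$time,
                                              msd = msd_series_2d(series)),
                        inherit.aes = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time", y = "mean-square displacement (2D)",
      title = sprintf("crossover fit (%s): alpha = %.3g, Gamma = %.3g",
                      object$method, object$alpha, object$gamma),
      colour = NULL, linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the crossover curves of the forward model
#'
#' Two companion views of the model for one or more exponents: the
#' normalized MSD `<r^2>/lambda^2` against `t/tau` with the ballistic and
#' Brownian reference lines (`plot_msd_crossover()`), and the advancement
#' `<r^2> / (4 Gamma t^alpha)` against `t/tau` showing the roughly
#' three-decade ballistic-to-anomalous transition
#' (`plot_msd_advancement()`).
#'
#' @param alphas Anomalous exponents to draw.
#' @param t_over_tau Range of `t/tau`, length 2.
#' @param n Points per curve.
#' @return A ggplot object.
#' @export
plot_msd_crossover <- function(alphas = c(0.5, 0.75, 1, 1.5, 2),
                               t_over_tau = c(1e-3, 1e6), n = 200) {
  grid <- 10^seq(log10(t_over_tau[1]), log10(t_over_tau[2]), length.out = n)
  df <- purrr::map_dfr(alphas, function(a) {
    tibble::tibble(t_over_tau = grid, alpha = a,
                   y = msd_normalized(grid, a))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_over_tau, y = .data$y,
                                   colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t / tau", y = "<r^2> / lambda^2", colour = "alpha") +
    ggplot2::theme_minimal()
}

#' @rdname plot_msd_crossover
#' @export
plot_msd_advancement <- function(alphas = c(0.5, 0.75, 1),
                                 t_over_tau = c(1e-2, 1e8), n = 200) {
  grid <- 10^seq(log10(t_over_tau[1]), log10(t_over_tau[2]), length.out = n)
  df <- purrr::map_dfr(alphas, function(a) {
    y <- msd_normalized(grid, a)
    tibble::tibble(t_over_tau = grid, alpha = a,
                   advancement = 2^(a - 2) * y * grid^(-a))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_over_tau,
                                   y = .data$advancement,
                                   colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t / tau", y = "<r^2> / (4 Gamma t^alpha)",
                  colour = "alpha") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
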