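test_that("two-point mean-free-path estimator is exact on model data", {
  # hand-checkable case: t/tau = 4 and 12 with lambda = tau = 1
  expect_equal(estimate_lambda_two_point(t1 = 4, msd1 = 4, t2 = 12, msd2 = 16), 1)
  # dimensional homogeneity: scaling msd by c^2 scales lambda by c
  expect_equal(
    estimate_lambda_two_point(t1 = 4, msd1 = 4 * 9, t2 = 12, msd2 = 16 * 9), 3)
  # exact (not asymptotic) for any pair drawn from the ordinary model
  set.seed(7)
  for (i in 1:25) {
    p <- walk_params(stats::runif(1, 0.05, 5), stats::runif(1, 1e-4, 2),
                     alpha = 1)
    t1 <- p$tau * stats::runif(1, 0.1, 50)
    t2 <- t1 * stats::runif(1, 1.5, 50)
    lam <- estimate_lambda_two_point(t1 = t1, msd1 = msd(t1, p),
                                     t2 = t2, msd2 = msd(t2, p))
    expect_equal(lam, p$lambda, tolerance = 1e-8)
  }
  # data-frame interface uses first and last rows
  p <- walk_params(0.3, 0.01, alpha = 1)
  d <- tibble::tibble(time = c(0.035, 0.07, 0.14), msd = msd(time, p))
  expect_equal(estimate_lambda_two_point(d), 0.3, tolerance = 1e-8)
})

test_that("two-point estimator rejects degenerate and inconsistent data", {
  # exactly ballistic pair: sqrt(msd) proportional to t
  expect_error(
    estimate_lambda_two_point(t1 = 1, msd1 = 4, t2 = 2, msd2 = 16),
    "ballistic")
  # faster-than-ballistic growth implies a negative mean free path
  expect_error(
    estimate_lambda_two_point(t1 = 1, msd1 = 4, t2 = 2, msd2 = 30),
    "inconsistent")
  expect_error(estimate_lambda_two_point(t1 = 2, msd1 = 4, t2 = 1, msd2 = 16),
               "t1 < t2")
})

test_that("step-time estimators invert their defining relations", {
  expect_equal(tau_from_lambda_D(1, 0.5), 1)
  expect_equal(tau_from_lambda_D(0.0559, 4.15), 3.77e-4, tolerance = 0.005)
  # round trip with the diffusion coefficient
  p <- walk_params(0.42, 0.037)
  expect_equal(tau_from_lambda_D(p$lambda, diffusion_coefficient(p)), p$tau)

  # anomalous/normal ratio route, super-diffusive water-in-porous-glass case
  expect_equal(tau_from_anomalous_ratio(8.5, 1.95, 0.3), 1.58e-2,
               tolerance = 0.005)
  expect_equal(tau_from_anomalous_ratio(1, 1.4, 6), 3)   # ratio 1 -> t/2
  expect_error(tau_from_anomalous_ratio(2, 1, 1), "singular")
  expect_error(tau_from_anomalous_ratio(-2, 1.5, 1), "ratio")
  # forward-generated ratio (2 tau / t)^(1 - alpha) recovers tau
  for (a in c(0.5, 1.6)) {
    tau <- 0.02; t <- 0.9
    ratio <- (2 * tau / t)^(1 - a)
    expect_equal(tau_from_anomalous_ratio(ratio, a, t), tau, tolerance = 1e-12)
  }
})

test_that("transport ratio from MSD ratio matches the closure identities", {
  expect_equal(gamma_over_D_from_ratio(8.5, 1.95, 0.3), 27, tolerance = 0.5 / 27)
  expect_equal(gamma_over_D_from_ratio(3.2, 1, 5), 3.2)   # alpha = 1 passthrough
  # with tau from the same inputs, the universal coordinate is exact
  ratio <- 8.5; a <- 1.95; t <- 0.3
  tau <- tau_from_anomalous_ratio(ratio, a, t)
  expect_equal(gamma_over_D_from_ratio(ratio, a, t) * tau^(a - 1), 2^(1 - a),
               tolerance = 1e-12)
})

test_that("single-point exponent estimator round-trips the forward model", {
  truth <- walk_params(1, 1, alpha = 0.7)
  fit <- alpha_from_single_point(lambda = 1, tau = 1, t = 100,
                                 obs = msd(100, truth))
  expect_s3_class(fit, "msd_fit")
  expect_equal(fit$alpha, 0.7, tolerance = 1e-6)
  expect_identical(fit$method, "single_point")
  expect_identical(fit$residual_norm, 0)
  # ordinary diffusion: alpha = 1 and Gamma = D
  p1 <- walk_params(0.4, 0.02, alpha = 1)
  f1 <- alpha_from_single_point(lambda = 0.4, tau = 0.02, t = 1,
                                obs = msd(1, p1))
  expect_equal(f1$alpha, 1, tolerance = 1e-8)
  expect_equal(f1$gamma, diffusion_coefficient(p1), tolerance = 1e-8)
  # infeasible: at or above the ballistic bound
  expect_error(
    alpha_from_single_point(lambda = 1, tau = 1, t = 10, obs = 101),
    "ballistic bound")
})

test_that("single-point estimator reproduces the shortest-time membrane fit", {
  # observation reconstructed from the printed normalized value:
  # msd = 0.803 * 4 Gamma t^alpha with alpha = 0.862, Gamma = 1.54
  obs <- 0.803 * 4 * 1.54 * 0.035^0.862
  fit <- alpha_from_single_point(lambda = 0.0559, tau = 3.77e-4,
                                 t = 0.035, obs = obs)
  expect_equal(fit$alpha, 0.862, tolerance = 0.01)
  expect_equal(fit$gamma, 1.54, tolerance = 0.01)
})

test_that("every calibrated fit lands exactly on the Gamma/D closure curve", {
  lam <- 0.0559; tau <- 3.77e-4; D <- lam^2 / (2 * tau)
  fits <- list(
    alpha_from_single_point(lambda = lam, tau = tau, t = 0.035,
                            obs = 0.803 * 4 * 1.54 * 0.035^0.862),
    fit_alpha_gamma(
      generate_msd_series(walk_params(lam, tau, 0.77),
                          c(0.035, 0.07, 0.105, 0.14), cv = 0.03, seed = 5),
      lambda = lam, tau = tau)
  )
  for (f in fits) {
    expect_equal(f$gamma, D * (2 * tau)^(1 - f$alpha), tolerance = 1e-12)
    expect_equal(f$gamma, 2^(-f$alpha) * lam^2 / tau^f$alpha, tolerance = 1e-12)
  }
  # the membrane study's three best-fit pairs lie on the same curve
  pairs <- list(c(0.871, 1.64), c(0.780, 0.854), c(0.573, 0.193))
  for (pa in pairs) {
    expect_equal(D * (2 * tau)^(1 - pa[1]), pa[2], tolerance = 0.005)
  }
})

test_that("calibrated least-squares fit recovers alpha from noiseless data", {
  p <- walk_params(1, 0.01, alpha = 0.78)
  d <- tibble::tibble(time = c(0.035, 0.07, 0.105, 0.14), msd = msd(time, p))
  fit <- fit_alpha_gamma(d, lambda = 1, tau = 0.01)
  expect_equal(fit$alpha, 0.78, tolerance = 1e-7)
  expect_identical(fit$method, "least_squares")
  expect_false(fit$at_boundary)
  expect_lt(fit$residual_norm, 1e-7)
  # alpha = 1 noiseless series gives Gamma = D to high accuracy
  p1 <- walk_params(0.5, 0.002, alpha = 1)
  d1 <- tibble::tibble(time = c(0.01, 0.02, 0.04, 0.08), msd = msd(time, p1))
  f1 <- fit_alpha_gamma(d1, lambda = 0.5, tau = 0.002)
  expect_equal(f1$gamma, diffusion_coefficient(p1), tolerance = 1e-8)
  expect_error(fit_alpha_gamma(d1[1, ], 0.5, 0.002), "at least two")
})

test_that("a ballistic series pins the fit at the alpha boundary and flags it", {
  p2 <- walk_params(1, 1, alpha = 2)
  d <- tibble::tibble(time = c(0.1, 0.2, 0.4), msd = msd(time, p2))
  fit <- fit_alpha_gamma(d, lambda = 1, tau = 1)
  expect_equal(fit$alpha, 2)
  expect_true(fit$at_boundary)
})

test_that("noisy-series fits recover the exponent without material bias", {
  # multiplicative noise CV 2% on the four-time grid; mean alpha-hat close
  # to truth across seeds
  lam <- 1; tau <- 0.01; a <- 0.8
  p <- walk_params(lam, tau, a)
  times <- c(0.035, 0.07, 0.105, 0.14)
  alphas <- vapply(1:200, function(s) {
    d <- generate_msd_series(p, times, cv = 0.02, seed = s)
    fit_alpha_gamma(d, lambda = lam, tau = tau)$alpha
  }, numeric(1))
  expect_lt(abs(mean(alphas) - a), 0.02)
})

test_that("fitting the full model to asymptotic-law data overshoots alpha", {
  # Data generated from the long-time power law alone, at times where the
  # crossover is still in progress, exceed the full model everywhere
  # (normalized MSD < 1), so the calibrated fit must inflate alpha to
  # compensate: the asymptotic law is not a substitute for the full
  # equation on short-period data.
  lam <- 1; tau <- 0.01; a <- 0.7
  p <- walk_params(lam, tau, a)
  times <- tau * c(2, 5, 10, 20, 30)
  d <- tibble::tibble(time = times, msd = msd_longtime(times, p))
  fit <- fit_alpha_gamma(d, lambda = lam, tau = tau)
  expect_gt(fit$alpha, a + 0.05)
})

test_that("free two-parameter fit recovers sub- and super-diffusive pairs", {
  # sub-diffusive pair from the membrane study scale
  D <- 4.15
  tau <- ((1.64 / D)^(1 / (1 - 0.871))) / 2
  p <- walk_params(sqrt(2 * D * tau), tau, 0.871)
  d <- tibble::tibble(time = c(0.035, 0.07, 0.105, 0.14), msd = msd(time, p))
  fit <- fit_free(d, D = D)
  expect_equal(fit$alpha, 0.871, tolerance = 1e-4)
  expect_equal(fit$gamma, 1.64, tolerance = 1e-3)
  expect_identical(fit$method, "free_fit")
  # implied step time matches the independent calibration
  expect_equal(fit$tau_implied, 3.77e-4, tolerance = 0.01)

  # super-diffusive branch
  ps <- walk_params(0.1, 0.001, alpha = 1.5)
  ds <- tibble::tibble(time = 10^seq(-2, 1, length.out = 6),
                       msd = msd(time, ps))
  fs <- fit_free(ds, D = diffusion_coefficient(ps))
  expect_equal(fs$alpha, 1.5, tolerance = 1e-4)
  expect_equal(fs$gamma, transport_coefficient(ps), tolerance = 1e-4)

  expect_error(fit_free(d[1:2, ], D = D), "three")
})

test_that("fit objects expose tidy and glance views", {
  p <- walk_params(1, 0.01, alpha = 0.78)
  d <- tibble::tibble(time = c(0.035, 0.07, 0.105, 0.14), msd = msd(time, p))
  fit <- fit_alpha_gamma(d, lambda = 1, tau = 0.01)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("alpha", "gamma", "v0"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$alpha, fit$alpha)
  expect_equal(gl$n_points, 4L)
  expect_output(print(fit), "least_squares")
})
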