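test_that("ARMA(1,1) correlation matches closed forms and its simulated process", {
  # AR(1) limit
  expect_equal(arma11_correlation(0.8, 0, 3), 0.8^3)
  # MA(1) vanishes beyond lag 1
  expect_equal(arma11_correlation(0, 0.5, 2), 0)
  expect_equal(arma11_correlation(0, 0.5, 1), 0.5 / 1.25)
  # closed form at phi = 0.9, theta = 0.3
  expect_equal(arma11_correlation(0.9, 0.3, 1),
               (1 + 0.27) * 1.2 / (1 + 0.54 + 0.09), tolerance = 1e-12)
  expect_error(arma11_correlation(1.2, 0, 1), "non-stationary")
  expect_error(arma11_correlation(0.5, 0, -1), ">= 0")

  # empirical ACF of a long simulated ARMA(1,1) path as independent oracle
  set.seed(1)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9, ma = 0.3), n = 200000))
  emp <- stats::acf(x, lag.max = 3, plot = FALSE)$acf[2:4]
  expect_equal(emp, arma11_correlation(0.9, 0.3, 1:3), tolerance = 0.02)
})

test_that("REML likelihood equals a dense multivariate-normal evaluation", {
  set.seed(2)
  d <- simulate_arma_panel(3, 6, beta = c(x = 0.5), sigma_b = 1.5,
                           sigma = 1, phi = 0.6, theta = 0.2, seed = 4)
  # punch a gap into one patient so observed-offset handling is exercised
  d <- d[-5, ]
  y <- d$y
  X <- cbind(1, d$x)
  prep <- neuromd:::.reml_prepare(y, X, d$patient_id, d$hour_index)
  for (pars in list(c(1.5, 1, 0.6, 0.2), c(0.5, 2, -0.3, 0.4),
                    c(2, 0.7, 0.9, -0.2))) {
    mine <- neuromd:::.reml_neg2ll_at(pars[1], pars[2], pars[3], pars[4],
                                      prep)$value
    brute <- brute_reml_neg2ll(y, X, d$patient_id, d$hour_index,
                               pars[1], pars[2], pars[3], pars[4])
    expect_equal(mine, brute, tolerance = 1e-8)
  }
})

test_that("degenerate covariance settings reduce the fit to ordinary least squares", {
  d <- simulate_arma_panel(8, 12, beta = c(x = 1.2), sigma_b = 1,
                           sigma = 1, phi = 0.5, theta = 0, seed = 5)
  f <- fit_reml(d, "y", "x", fixed = list(sigma_b = 0, phi = 0, theta = 0))
  ols <- lm(y ~ x, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-8)
  expect_equal(f$coefficients$std_error,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-8)
})

test_that("one observation per patient reduces to OLS with matching standard errors", {
  set.seed(6)
  d <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                      hour_index = 0L, x = rnorm(30),
                      y = 1 + 0.8 * rnorm(30) + 0.5 * x)
  f <- fit_reml(d, "y", "x", fixed = list(phi = 0, theta = 0))
  ols <- lm(y ~ x, data = d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(f$coefficients$std_error,
               unname(summary(ols)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("parameters are recovered from a generated panel", {
  d <- simulate_arma_panel(40, 60, beta = c(x = 0.5), sigma_b = 2,
                           sigma = 1, phi = 0.8, theta = 0.2, seed = 7)
  f <- fit_reml(d, "y", "x", n_starts = 1)
  expect_equal(f$sigma_b, 2, tolerance = 0.25)
  expect_equal(f$sigma, 1, tolerance = 0.1)
  expect_equal(f$phi, 0.8, tolerance = 0.08)
  expect_equal(f$theta, 0.2, tolerance = 0.12)
  expect_equal(f$coefficients$estimate[2], 0.5, tolerance = 0.05)
  expect_true(f$convergence$converged)
})

test_that("the fit agrees with an independent REML implementation (nlme)", {
  skip_if_not_installed("nlme")
  d <- simulate_arma_panel(15, 40, beta = c(x = 0.7), sigma_b = 1.5,
                           sigma = 1, phi = 0.7, theta = 0.1, seed = 8)
  f <- fit_reml(d, "y", "x", n_starts = 2)
  ref <- nlme::lme(y ~ x, random = ~ 1 | patient_id,
                   correlation = nlme::corARMA(p = 1, q = 1,
                                               form = ~ hour_index | patient_id),
                   data = d, method = "REML")
  expect_equal(f$coefficients$estimate, unname(nlme::fixef(ref)),
               tolerance = 1e-3)
  cs <- coef(ref$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(f$phi, unname(cs[1]), tolerance = 0.02)
  expect_equal(f$theta, unname(cs[2]), tolerance = 0.05)
  expect_equal(f$sigma, ref$sigma, tolerance = 0.02)
})

test_that("reported adjacent-hour correlation tracks the generating process", {
  d <- simulate_arma_panel(40, 60, beta = c(x = 0.3), sigma_b = 1.5,
                           sigma = 1, phi = 0.85, theta = 0.1, seed = 9)
  f <- fit_reml(d, "y", "x", n_starts = 1)
  expect_equal(f$rho1, arma11_correlation(0.85, 0.1, 1), tolerance = 0.03)
})

test_that("effect-size report is the coefficient-perturbation product", {
  d <- simulate_arma_panel(10, 20, beta = c(x = 0.5), seed = 10)
  f <- fit_reml(d, "y", "x", n_starts = 1)
  es <- effect_size_report(f, c(x = 2))
  b <- f$coefficients$estimate[f$coefficients$term == "x"]
  expect_equal(es$delta, 2 * b)
  expect_error(effect_size_report(f, c(bogus = 1)), "unknown terms")
  # zero coefficient gives zero predicted change
  f0 <- f
  f0$coefficients$estimate[2] <- 0
  expect_equal(effect_size_report(f0, c(x = 5))$delta, 0)
})

test_that("collinear or constant predictors are rejected", {
  d <- simulate_arma_panel(8, 10, beta = c(x = 0.5), seed = 11)
  d$x2 <- 2 * d$x
  expect_error(fit_reml(d, "y", c("x", "x2")), "collinear")
  d$x3 <- 1
  expect_error(fit_reml(d, "y", "x3"), "constant predictor")
})
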