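stub_frame <- function(values, patient = "P01", hours = seq_along(values) - 1L,
                       icp = 12, cpp = 70) {
  n <- length(values)
  tibble::tibble(patient_id = patient, location = "pericontusional",
                 hour_index = as.integer(hours),
                 glucose_t = values, lactate_t = values, pyruvate_t = values,
                 glycerol_t = values, lp_ratio = values, lg_ratio = values,
                 icp_hour = rep(icp, length.out = n),
                 cpp_hour = rep(cpp, length.out = n))
}

test_that("differencing matches arithmetic and respects exact k-hour gaps", {
  d <- stub_frame(c(1, 2, 4))
  dd <- difference_series(d, 1)
  expect_equal(dd$d_lactate_t, c(1, 2))
  expect_equal(difference_series(stub_frame(rep(5, 6)), 1)$d_lactate_t,
               rep(0, 5))
  expect_error(difference_series(d, 5), "1..4")

  # dropped middle hour: the pair spanning the 2-hour gap is excluded
  gap <- stub_frame(c(1, 2, 4), hours = c(0L, 1L, 3L))
  dd2 <- difference_series(gap, 1)
  expect_equal(nrow(dd2), 1L)
  expect_equal(dd2$d_lactate_t, 1)
  # ...but contributes to k = 2 pairing
  dd3 <- difference_series(gap, 2)
  expect_equal(dd3$d_lactate_t, 2)

  # k = 4 on a 5-hour patient leaves at most one pair
  expect_lte(nrow(difference_series(stub_frame(1:5), 4)), 1L)
})

test_that("summing first differences reconstructs the series", {
  set.seed(1)
  d <- stub_frame(rnorm(20))
  dd <- difference_series(d, 1)
  expect_equal(d$lactate_t[1] + cumsum(dd$d_lactate_t),
               d$lactate_t[-1], tolerance = 1e-12)
})

test_that("per-subject normalization gives mean 0 and SD 1 and kills identity variance", {
  set.seed(2)
  d <- dplyr::bind_rows(stub_frame(rnorm(30, 5), "P01"),
                        stub_frame(rnorm(30, 9, 3), "P02"))
  d$icp_hour <- rnorm(60, 14, 2)
  d$cpp_hour <- rnorm(60, 66, 4)
  nz <- normalize_per_subject(d)
  for (id in c("P01", "P02")) {
    expect_equal(mean(nz$lactate_t[nz$patient_id == id]), 0,
                 tolerance = 1e-12)
    expect_equal(sd(nz$lactate_t[nz$patient_id == id]), 1,
                 tolerance = 1e-12)
  }
  expect_lt(identity_variance(nz, "lactate_t")$r_squared, 1e-10)

  # hand-computed z-scores on a tiny fixture
  f <- dplyr::bind_rows(stub_frame(c(1, 2, 3), "A"),
                        stub_frame(c(10, 20, 40), "B"))
  f$icp_hour <- c(10, 12, 14, 10, 12, 14)
  f$cpp_hour <- c(60, 70, 80, 60, 70, 80)
  fz <- normalize_per_subject(f, columns = "lactate_t")
  expect_equal(fz$lactate_t[fz$patient_id == "A"], c(-1, 0, 1))
  expect_equal(fz$lactate_t[fz$patient_id == "B"],
               (c(10, 20, 40) - mean(c(10, 20, 40))) / sd(c(10, 20, 40)))

  # zero-SD patient dropped with a warning
  g <- dplyr::bind_rows(f, stub_frame(rep(2, 3), "C"))
  expect_warning(out <- normalize_per_subject(g, columns = "lactate_t"),
                 "zero within-patient SD")
  expect_false("C" %in% out$patient_id)
})

test_that("normalized analyses are invariant to per-patient affine rescaling", {
  set.seed(3)
  d <- dplyr::bind_rows(stub_frame(rnorm(25, 5), "P01"),
                        stub_frame(rnorm(25, 7), "P02"))
  d$icp_hour <- rnorm(50, 14, 2)
  d$cpp_hour <- rnorm(50, 66, 4)
  d2 <- d
  d2$lactate_t[d2$patient_id == "P01"] <-
    3 * d2$lactate_t[d2$patient_id == "P01"] + 10
  d2$lactate_t[d2$patient_id == "P02"] <-
    0.2 * d2$lactate_t[d2$patient_id == "P02"] - 4
  n1 <- normalize_per_subject(d, columns = c("lactate_t", "icp_hour"))
  n2 <- normalize_per_subject(d2, columns = c("lactate_t", "icp_hour"))
  expect_equal(n1$lactate_t, n2$lactate_t, tolerance = 1e-10)
})

test_that("the OLS probe matches a hand-rolled normal-equations oracle", {
  set.seed(4)
  n <- 18
  d <- tibble::tibble(patient_id = sprintf("P%02d", 1:n),
                      x1 = rnorm(n), x2 = rnorm(n),
                      y = 1 + 2 * rnorm(n))
  rr <- regress(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(rr$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  fitted <- X %*% beta
  r2 <- 1 - sum((d$y - fitted)^2) / sum((d$y - mean(d$y))^2)
  expect_equal(rr$r_squared, r2, tolerance = 1e-10)

  # perfect linear signal (summary() warns about the exact fit by design)
  d$y <- 3 * d$x1
  rr2 <- suppressWarnings(regress(d, "y", "x1"))
  expect_equal(rr2$coefficients$estimate[2], 3, tolerance = 1e-10)
  expect_equal(rr2$r_squared, 1, tolerance = 1e-10)
})

test_that("Cook's screening matches the leverage formula and excludes on refit", {
  set.seed(5)
  x <- c(rnorm(9), 10)
  y <- c(2 * x[1:9] + rnorm(9, sd = 0.3), -20)
  d <- tibble::tibble(patient_id = sprintf("P%02d", 1:10), x = x, y = y)
  cd <- brute_cooks(matrix(x), y)
  expect_equal(unname(cooks.distance(lm(y ~ x))), cd, tolerance = 1e-10)
  expect_gt(cd[10], 1)
  rr <- regress(d, "y", "x", mode = "subject_means")
  expect_equal(rr$excluded$patient_id, "P10")
  expect_equal(rr$excluded$cooks_distance, cd[10], tolerance = 1e-10)
  expect_equal(rr$n, 9L)
  expect_equal(rr$coefficients$estimate[2], 2, tolerance = 0.2)
  # the pre-exclusion fit is retained for comparison
  expect_equal(rr$initial$n, 10L)
})

test_that("subject-means significance is tested against the number of patients", {
  set.seed(6)
  n_pat <- 12
  d <- tibble::tibble(patient_id = sprintf("P%02d", 1:n_pat),
                      x = rnorm(n_pat), y = rnorm(n_pat))
  rr <- regress(d, "y", "x", mode = "subject_means")
  ref <- summary(lm(y ~ x, data = d))$coefficients
  expect_equal(rr$coefficients$p_value, unname(ref[, 4]), tolerance = 1e-12)
  expect_error(regress(dplyr::bind_rows(d, d), "y", "x",
                       mode = "subject_means"), "one row per patient")
})

test_that("instantaneous difference coupling is detected by the delta-delta design", {
  set.seed(7)
  rows <- lapply(1:12, function(i) {
    cpp <- 66 + as.numeric(stats::filter(rnorm(40, sd = 3), 0.8,
                                         method = "recursive"))
    f <- stub_frame(rnorm(40, 5), sprintf("P%02d", i))
    f$cpp_hour <- cpp
    f$icp_hour <- rnorm(40, 14, 2)
    dl <- c(0, diff(cpp))
    f$lactate_t <- 5 + 0.3 * dl + rnorm(40, sd = 0.2)
    f
  })
  d <- dplyr::bind_rows(rows)
  dr <- delta_report(d, ks = 1, by_location = FALSE)
  dd_row <- dr[dr$design == "d_lactate_t" & dr$pairing == "difference" &
                 dr$response == "cpp", ]
  lvl_row <- dr[dr$design == "d_lactate_t" & dr$pairing == "level" &
                  dr$response == "cpp", ]
  expect_gt(dd_row$r_squared, lvl_row$r_squared)
  expect_lt(dd_row$p_value, 0.01)
  expect_true(all(c("p_value", "p_holm") %in% names(dr)))
})
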