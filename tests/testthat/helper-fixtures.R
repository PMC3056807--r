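# Shared fixtures and independent brute-force oracles used across tests.

marker_zero <- c(glucose = 0, lactate = 0, pyruvate = 0, glycerol = 0)

marker_vec <- function(...) {
  v <- marker_zero
  a <- c(...)
  v[names(a)] <- a
  v
}

# Small cohort config with overridable pieces.
tiny_config <- function(n_patients = 10, hours_mean = 30, seed = 1, ...) {
  cohort_config(n_patients = n_patients, hours_mean = hours_mean,
                seed = seed, ...)
}

# Hand-built aligned-style frame: patients x hours grid with supplied value
# generator, regular hourly spacing, hour_index 0..(hours-1).
make_panel <- function(n_patients, n_hours, value_fun,
                       ids = sprintf("P%02d", seq_len(n_patients))) {
  rows <- lapply(seq_len(n_patients), function(i) {
    tibble::tibble(patient_id = ids[i], hour_index = 0:(n_hours - 1),
                   value = value_fun(i, n_hours))
  })
  dplyr::bind_rows(rows)
}

# Brute-force lagged cross-correlation on a small frame: explicit loops over
# every (patient, hour) pair, independent of the package's index machinery.
brute_ccf <- function(data, xcol, ycol, lag) {
  xs <- c()
  ys <- c()
  for (i in seq_len(nrow(data))) {
    j <- which(data$patient_id == data$patient_id[i] &
                 data$hour_index == data$hour_index[i] + lag)
    if (length(j) == 1) {
      xs <- c(xs, data[[xcol]][i])
      ys <- c(ys, data[[ycol]][j])
    }
  }
  if (length(xs) < 2) return(NA_real_)
  cor(xs, ys)
}

# Dense multivariate-normal REML evaluation: builds the full block-diagonal
# covariance and uses generic determinant() and solve() throughout.
brute_reml_neg2ll <- function(y, X, pid, hours, sigma_b, sigma, phi, theta) {
  ord <- order(pid, hours)
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  pid <- pid[ord]
  hours <- hours[ord]
  n <- length(y)
  p <- ncol(X)
  V <- matrix(0, n, n)
  for (id in unique(pid)) {
    i <- which(pid == id)
    h <- hours[i]
    R <- outer(h, h, function(a, b) {
      k <- abs(a - b)
      ifelse(k == 0, 1,
             (1 + phi * theta) * (phi + theta) /
               (1 + 2 * phi * theta + theta^2) * phi^(pmax(k, 1) - 1))
    })
    V[i, i] <- sigma^2 * R + sigma_b^2
  }
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Vi %*% r)
  as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    as.numeric(determinant(XtVX, logarithm = TRUE)$modulus) +
    quad + (n - p) * log(2 * pi)
}

# Textbook one-way ANOVA F from explicit sums of squares.
brute_anova_F <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ss_between <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                           numeric(1)))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  (ss_between / df1) / (ss_within / df2)
}

# Tie-corrected Kruskal-Wallis H from explicit rank arithmetic.
brute_kw_H <- function(values, groups) {
  rk <- rank(values)
  g <- split(rk, groups)
  n <- length(values)
  H <- 12 / (n * (n + 1)) *
    sum(vapply(g, function(v) length(v) * mean(v)^2, numeric(1))) -
    3 * (n + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Cook's distance via the direct leverage formula.
brute_cooks <- function(X, y) {
  Xb <- cbind(1, X)
  H <- Xb %*% solve(crossprod(Xb), t(Xb))
  h <- diag(H)
  e <- y - H %*% y
  p <- ncol(Xb)
  s2 <- sum(e^2) / (length(y) - p)
  as.numeric((e^2 / (p * s2)) * (h / (1 - h)^2))
}
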