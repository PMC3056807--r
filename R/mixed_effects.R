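# REML linear mixed models with patient random intercepts and ARMA(1,1)
# within-patient residual correlation, implemented directly from the
# restricted likelihood: per-patient covariance
#   V_i = sigma_b^2 * J + sigma^2 * R_i(phi, theta),
# with R_i built on the observed clock-hour offsets, beta profiled out by
# generalized least squares, and (sigma_b, sigma, phi, theta) optimized on
# unconstrained scales (log SDs, atanh correlations).

#' ARMA(1,1) autocorrelation at integer lags
#'
#' `rho(0) = 1`; for `k >= 1`,
#' `rho(k) = gamma * phi^(k-1)` with
#' `gamma = (1 + phi*theta) * (phi + theta) / (1 + 2*phi*theta + theta^2)`.
#' With `theta = 0` this reduces to the AR(1) `phi^k`; with `phi = 0` it
#' vanishes beyond lag 1.
#'
#' @param phi,theta stationary/invertible coefficients (|phi| < 1,
#'   |theta| < 1).
#' @param k non-negative integer lag(s).
#' @return correlation value(s).
#' @export
arma11_correlation <- function(phi, theta, k) {
  if (abs(phi) >= 1 || abs(theta) >= 1) {
    stop("non-stationary ARMA(1,1) parameters: need |phi| < 1 and |theta| < 1")
  }
  if (any(k < 0)) stop("lag k must be >= 0")
  gamma <- (1 + phi * theta) * (phi + theta) / (1 + 2 * phi * theta + theta^2)
  ifelse(k == 0, 1, gamma * phi^(pmax(k, 1) - 1))
}

# Group patients by identical hour-offset pattern so the per-patient
# correlation matrix (and its Cholesky factor) is computed once per pattern
# and all members are whitened in one triangular solve. Each pattern holds
# M = [X_1 | y_1 | X_2 | y_2 | ...] for its member patients.
.reml_prepare <- function(y, X, pid, hours) {
  gidx <- split(seq_along(y), pid)
  keys <- vapply(gidx, function(i) {
    h <- hours[i]
    paste(h - h[1], collapse = ",")
  }, character(1))
  patterns <- lapply(split(seq_along(gidx), keys), function(gs) {
    i1 <- gidx[[gs[1]]]
    h <- hours[i1]
    M <- do.call(cbind, lapply(gs, function(g) {
      i <- gidx[[g]]
      cbind(X[i, , drop = FALSE], y[i])
    }))
    list(h = h - h[1], M = M, m = length(gs))
  })
  list(patterns = patterns, n = length(y), p = ncol(X),
       n_patients = length(gidx))
}

# -2 * REML log-likelihood with the overall scale sigma^2 profiled out.
# lambda = sigma_b^2 / sigma^2. Returns the profiled objective plus the GLS
# beta, its covariance, and the profiled sigma / sigma_b.
.reml_profiled <- function(lambda, phi, theta, prep) {
  if (!is.finite(lambda) || lambda < 0) return(list(value = Inf))
  n <- prep$n
  p <- prep$p
  max_h <- max(vapply(prep$patterns, function(g) max(g$h), numeric(1)))
  rho <- arma11_correlation(phi, theta, 0:max(max_h, 1))
  logdet <- 0
  XtX <- matrix(0, p, p)
  Xty <- numeric(p)
  yty <- 0
  pc <- p + 1L
  for (g in prep$patterns) {
    off <- abs(outer(g$h, g$h, "-")) + 1L
    W <- matrix(rho[off], nrow(off), ncol(off)) + lambda
    C <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(C)) return(list(value = Inf))
    logdet <- logdet + g$m * 2 * sum(log(diag(C)))
    Z <- backsolve(C, g$M, transpose = TRUE)
    for (j in seq_len(g$m)) {
      ZX <- Z[, ((j - 1) * pc + 1):((j - 1) * pc + p), drop = FALSE]
      Zy <- Z[, j * pc]
      XtX <- XtX + crossprod(ZX)
      Xty <- Xty + as.numeric(crossprod(ZX, Zy))
      yty <- yty + sum(Zy^2)
    }
  }
  ch_xtx <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(ch_xtx)) return(list(value = Inf))
  beta <- backsolve(ch_xtx, backsolve(ch_xtx, Xty, transpose = TRUE))
  quad <- yty - sum(Xty * beta)
  if (quad <= 0) return(list(value = Inf))
  sigma2 <- quad / (n - p)
  val <- (n - p) * log(sigma2) + logdet + 2 * sum(log(diag(ch_xtx))) +
    (n - p) + (n - p) * log(2 * pi)
  list(value = val, beta = beta,
       cov_beta = sigma2 * chol2inv(ch_xtx),
       sigma = sqrt(sigma2), sigma_b = sqrt(sigma2 * lambda))
}

# Unprofiled evaluation at explicit (sigma_b, sigma): the profiled objective
# is evaluated at lambda and the scale term corrected back. Used when sigma
# itself is pinned and for external likelihood cross-checks.
.reml_neg2ll_at <- function(sigma_b, sigma, phi, theta, prep) {
  lam <- (sigma_b / sigma)^2
  base <- .reml_profiled(lam, phi, theta, prep)
  if (!is.finite(base$value)) return(base)
  n <- prep$n
  p <- prep$p
  quad <- base$sigma^2 * (n - p)
  struct_part <- base$value - (n - p) * (1 + log(2 * pi)) -
    (n - p) * log(base$sigma^2)
  val <- struct_part + (n - p) * log(sigma^2) + quad / sigma^2 +
    (n - p) * log(2 * pi)
  list(value = val, beta = base$beta,
       cov_beta = base$cov_beta / base$sigma^2 * sigma^2,
       sigma = sigma, sigma_b = sigma_b)
}

#' Fit a REML mixed model with ARMA(1,1) within-patient correlation
#'
#' Predicts a pressure summary (or any panel response) from microdialysis
#' predictors with a patient random intercept and ARMA(1,1) residual
#' correlation over observed clock-hour offsets, so correlation decays
#' correctly across gaps left by dropped rows. Fixed effects are profiled
#' out by GLS inside the restricted likelihood; Wald z tests are reported.
#' Predictors are standardized before fitting and coefficients back-scaled
#' for reporting.
#'
#' @param data tibble with `patient_id`, `hour_index`, the response and
#'   predictors (e.g. an aligned frame).
#' @param response response column (e.g. `"icp_hour"` or `"cpp_hour"`).
#' @param predictors character vector of predictor columns.
#' @param stratum optional value of `data$location` to subset to.
#' @param standardize center/scale predictors internally (default TRUE).
#' @param fixed optional named list pinning any of `sigma_b`, `sigma`,
#'   `phi`, `theta` at a given value (e.g.
#'   `list(sigma_b = 0, phi = 0, theta = 0)` reduces the fit to OLS).
#' @param n_starts number of optimizer starts (different initial `phi`).
#' @param grad_tol gradient-norm threshold for the convergence diagnostic.
#' @return object of class `mixed_fit`: coefficient table, `sigma_b`,
#'   `sigma`, `phi`, `theta`, implied adjacent-hour residual correlation
#'   `rho1`, REML log-likelihood, convergence diagnostics.
#' @export
fit_reml <- function(data, response, predictors, stratum = NULL,
                     standardize = TRUE, fixed = list(), n_starts = 3,
                     grad_tol = 1e-2) {
  if (!is.null(stratum)) data <- data[data$location %in% stratum, ]
  keep <- stats::complete.cases(data[, c(response, predictors)])
  data <- data[keep, ]
  ids <- unique(data$patient_id)
  if (length(ids) < 5 && is.null(fixed$sigma_b)) {
    stop("fit_reml needs at least 5 patients")
  }
  y <- data[[response]]
  Xp <- as.matrix(data[, predictors, drop = FALSE])
  ctr <- rep(0, ncol(Xp))
  scl <- rep(1, ncol(Xp))
  if (standardize && ncol(Xp)) {
    ctr <- colMeans(Xp)
    scl <- apply(Xp, 2, sd)
    if (any(scl == 0)) stop("constant predictor: ", paste(
      predictors[scl == 0], collapse = ", "))
    Xp <- scale(Xp, center = ctr, scale = scl)
  }
  X <- cbind(`(Intercept)` = 1, Xp)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("collinear predictors: design rank ",
                               qrX$rank, " < ", ncol(X))
  n <- length(y)
  p <- ncol(X)

  ord <- order(data$patient_id, data$hour_index)
  y <- y[ord]
  X <- X[ord, , drop = FALSE]
  prep <- .reml_prepare(y, X, data$patient_id[ord], data$hour_index[ord])

  ols <- lm.fit(X, y)
  s2 <- sum(ols$residuals^2) / max(n - p, 1)

  has_sigma_fixed <- "sigma" %in% names(fixed)
  if (!has_sigma_fixed && !is.null(fixed$sigma_b) && fixed$sigma_b != 0) {
    stop("pinning sigma_b at a nonzero value requires pinning sigma too")
  }
  fixed_phi <- fixed$phi
  fixed_theta <- fixed$theta
  if (has_sigma_fixed) {
    free <- c(if (is.null(fixed$sigma_b)) "sigma_b",
              if (is.null(fixed_phi)) "phi",
              if (is.null(fixed_theta)) "theta")
    eval_par <- function(v) {
      sb <- if ("sigma_b" %in% free) unname(exp(v[match("sigma_b", free)])) else
        fixed$sigma_b
      ph <- if ("phi" %in% free) unname(tanh(v[match("phi", free)])) else fixed_phi
      th <- if ("theta" %in% free) unname(tanh(v[match("theta", free)])) else
        fixed_theta
      out <- .reml_neg2ll_at(sb, fixed$sigma, ph, th, prep)
      out$phi <- ph
      out$theta <- th
      out
    }
    init_fun <- function(ph) {
      c(sigma_b = log(sqrt(s2 / 2) + 1e-6), phi = atanh(ph),
        theta = atanh(0.05))[free]
    }
  } else {
    # overall scale profiled out; optimize lambda = (sigma_b / sigma)^2
    free <- c(if (is.null(fixed$sigma_b)) "lambda",
              if (is.null(fixed_phi)) "phi",
              if (is.null(fixed_theta)) "theta")
    eval_par <- function(v) {
      lam <- if ("lambda" %in% free) unname(exp(v[match("lambda", free)])) else 0
      ph <- if ("phi" %in% free) unname(tanh(v[match("phi", free)])) else fixed_phi
      th <- if ("theta" %in% free) unname(tanh(v[match("theta", free)])) else
        fixed_theta
      out <- .reml_profiled(lam, ph, th, prep)
      out$phi <- ph
      out$theta <- th
      out
    }
    init_fun <- function(ph) {
      c(lambda = 0, phi = atanh(ph), theta = atanh(0.05))[free]
    }
  }
  objective <- function(v) eval_par(v)$value

  phi_starts <- if (is.null(fixed_phi)) {
    c(0.8, 0.4, 0.95, 0.2)[seq_len(max(n_starts, 1))]
  } else 0.5
  best <- NULL
  for (ph in phi_starts) {
    v0 <- init_fun(ph)
    if (!length(v0)) {
      opt <- list(par = setNames(numeric(0), character(0)),
                  value = objective(numeric(0)), convergence = 0L)
    } else {
      if (length(v0) > 1) {
        opt <- optim(v0, objective, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-10))
        v0 <- opt$par
      }
      opt <- optim(v0, objective, method = "BFGS",
                   control = list(maxit = 100, reltol = 1e-12))
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  fit <- eval_par(best$par)

  grad_norm <- if (length(best$par)) {
    eps <- 1e-5
    g <- vapply(seq_along(best$par), function(j) {
      e <- numeric(length(best$par))
      e[j] <- eps
      (objective(best$par + e) - objective(best$par - e)) / (2 * eps)
    }, numeric(1))
    sqrt(sum(g^2))
  } else 0

  beta <- fit$beta
  # back-scale coefficients and their covariance to raw predictor units
  A <- diag(c(1, 1 / scl), nrow = p)
  if (p > 1) A[1, -1] <- -ctr / scl
  beta_raw <- unname(as.numeric(A %*% beta))
  cov_raw <- A %*% as.matrix(fit$cov_beta) %*% t(A)
  se_raw <- unname(sqrt(diag(cov_raw)))
  z <- beta_raw / se_raw
  coefs <- tibble::tibble(
    term = colnames(X), estimate = beta_raw, std_error = se_raw,
    z_value = z, p_value = 2 * pnorm(-abs(z)))

  structure(list(
    coefficients = coefs,
    sigma_b = fit$sigma_b, sigma = fit$sigma,
    phi = fit$phi, theta = fit$theta,
    rho1 = arma11_correlation(fit$phi, fit$theta, 1),
    logLik = -0.5 * fit$value,
    response = response, predictors = predictors, stratum = stratum,
    n = n, n_patients = prep$n_patients,
    convergence = list(code = best$convergence, neg2ll = best$value,
                       grad_norm = grad_norm,
                       converged = grad_norm < grad_tol * max(1, abs(best$value)))),
    class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("REML mixed model: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  if (!is.null(x$stratum)) cat("stratum:", x$stratum, "\n")
  cat(sprintf("n = %d rows, %d patients\n", x$n, x$n_patients))
  cat(sprintf(
    "sigma_b = %.4f  sigma = %.4f  phi = %.4f  theta = %.4f  rho(1) = %.4f\n",
    x$sigma_b, x$sigma, x$phi, x$theta, x$rho1))
  cat(sprintf("REML logLik = %.4f\n", x$logLik))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Predicted pressure change for a microdialysis perturbation
#'
#' Multiplies fitted fixed-effect coefficients by a hypothetical predictor
#' perturbation (for instance the 5th-to-95th percentile span of a marker)
#' to express effect sizes in mmHg.
#'
#' @param fit a `mixed_fit`.
#' @param md_perturbation named numeric vector of predictor changes (raw
#'   predictor units).
#' @param level confidence level for the Wald interval.
#' @return tibble with term, perturbation, predicted delta and CI.
#' @export
effect_size_report <- function(fit, md_perturbation, level = 0.95) {
  stopifnot(inherits(fit, "mixed_fit"))
  co <- fit$coefficients
  terms <- names(md_perturbation)
  bad <- setdiff(terms, co$term)
  if (length(bad)) stop("unknown terms: ", paste(bad, collapse = ", "))
  i <- match(terms, co$term)
  zq <- -stats::qnorm((1 - level) / 2)
  tibble::tibble(
    term = terms,
    perturbation = unname(md_perturbation),
    delta = co$estimate[i] * unname(md_perturbation),
    lower = (co$estimate[i] - zq * co$std_error[i]) * unname(md_perturbation),
    upper = (co$estimate[i] + zq * co$std_error[i]) * unname(md_perturbation))
}
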