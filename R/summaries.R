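# Descriptive surfaces: pooled binned tables, lowess scatter fits, and
# time-since-insertion trend checks.

#' Default pressure bin edges
#'
#' ICP bins: < 15, 15-20, 20-25, 25-30, > 30 mmHg. CPP bins: < 40 then
#' 10-mmHg steps to > 90.
#'
#' @param variable `"icp"` or `"cpp"`.
#' @return numeric vector of interior edges.
#' @export
default_bin_edges <- function(variable = c("icp", "cpp")) {
  variable <- match.arg(variable)
  if (variable == "icp") c(15, 20, 25, 30) else c(40, 50, 60, 70, 80, 90)
}

.bin_labels <- function(edges) {
  k <- length(edges)
  c(paste("<", edges[1]),
    if (k > 1) paste(edges[-k], "to", edges[-1]),
    paste(">", edges[k]))
}

#' Pooled microdialysis summaries binned by pressure interval
#'
#' Means and SDs of the raw-unit markers and ratios within pressure bins,
#' per catheter-location stratum. Pooled tables ignore the repeated-measures
#' structure: a patient's hours distribute unevenly over bins and can
#' dominate single bins, so these are descriptive only (the
#' `per_patient_weighted` variant lets each patient contribute its within-bin
#' mean once).
#'
#' @param data aligned tibble.
#' @param variable `"icp"` or `"cpp"` (uses `icp_hour` / `cpp_hour`).
#' @param edges ascending interior bin edges (mmHg).
#' @param per_patient_weighted average patients' bin-means instead of
#'   pooling samples?
#' @return tibble with location, bin, per-variable mean and sd columns, and
#'   `n` (samples, or patients contributing when weighted).
#' @export
bin_pooled <- function(data, variable = c("icp", "cpp"),
                       edges = NULL, per_patient_weighted = FALSE) {
  variable <- match.arg(variable)
  if (is.null(edges)) edges <- default_bin_edges(variable)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be ascending")
  x <- data[[paste0(variable, "_hour")]]
  labs <- .bin_labels(edges)
  bin <- cut(x, breaks = c(-Inf, edges, Inf), labels = labs, right = FALSE)
  vars <- c(MD_MARKERS, MD_RATIOS)
  d <- dplyr::mutate(data, .bin = bin,
                     location = factor(.data$location))
  if (!nrow(d)) {
    warning("empty stratum: no rows to bin")
    return(tibble::tibble())
  }
  if (per_patient_weighted) {
    d <- d |>
      dplyr::group_by(.data$location, .data$.bin, .data$patient_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(vars), mean),
                       .groups = "drop")
  }
  out <- d |>
    dplyr::group_by(.data$location, .data$.bin, .drop = FALSE) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(vars), list(mean = mean, sd = sd)),
      n = dplyr::n(), .groups = "drop")
  out <- dplyr::rename(out, bin = ".bin")
  out$location <- as.character(out$location)
  attr(out, "edges") <- edges
  attr(out, "variable") <- variable
  attr(out, "per_patient_weighted") <- per_patient_weighted
  out
}

# Tricube kernel on scaled distances in [0, 1).
.tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

#' Locally weighted scatterplot smoothing with a standard-error band
#'
#' Degree-1 local regression with tricube weights over a span-fraction
#' nearest-neighbour bandwidth, with bisquare robustness iterations, and a
#' pointwise SE band from the local weighted residual variance.
#'
#' @param x,y numeric vectors (at least 10 points).
#' @param span fraction of points in each local neighbourhood.
#' @param robust_iter number of bisquare robustness reweightings.
#' @param grid evaluation points; defaults to an even grid over
#'   `range(x)` of length `grid_n`.
#' @param grid_n grid size when `grid` is NULL.
#' @return tibble with `x`, `fitted`, `se`.
#' @export
lowess_fit <- function(x, y, span = 2 / 3, robust_iter = 2,
                       grid = NULL, grid_n = 50) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 10) stop("lowess_fit needs at least 10 points")
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = grid_n)
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  rw <- rep(1, n)

  local_fit <- function(x0, want_se = FALSE) {
    d <- abs(x - x0)
    h <- sort(d, partial = k)[k]
    if (h == 0) h <- max(d[d > 0][1], .Machine$double.eps)
    w <- .tricube(d / h) * rw
    if (sum(w > 0) < 2) {
      return(c(fit = NA_real_, se = NA_real_))
    }
    xc <- x - x0
    sw <- sum(w)
    mx <- sum(w * xc) / sw
    my <- sum(w * y) / sw
    sxx <- sum(w * (xc - mx)^2)
    beta <- if (sxx > 0) sum(w * (xc - mx) * (y - my)) / sxx else 0
    fit0 <- my - beta * mx
    if (!want_se) return(c(fit = fit0, se = NA_real_))
    res <- y - (my + beta * (xc - mx))
    nw <- sum(w)^2 / sum(w^2)  # effective local sample size
    s2 <- sum(w * res^2) / sum(w) * nw / max(nw - 2, 1)
    # variance of the fitted intercept at x0 under the local linear model
    var_fit <- s2 * (1 / nw + if (sxx > 0) mx^2 * sum(w) / sxx / nw else 0)
    c(fit = fit0, se = sqrt(var_fit))
  }

  for (it in seq_len(robust_iter)) {
    fit_at_x <- vapply(x, local_fit, numeric(2))[1, ]
    res <- y - fit_at_x
    s <- median(abs(res))
    rw <- if (s > 0) (1 - pmin((res / (6 * s))^2, 1))^2 else rep(1, n)
  }
  est <- vapply(grid, local_fit, numeric(2), want_se = TRUE)
  tibble::tibble(x = grid, fitted = est[1, ], se = est[2, ])
}

#' Check for time-since-insertion trends in the markers
#'
#' Fits pooled polynomials (orders 2 and 3 by default) of each transformed
#' marker on hours since catheter insertion and reports the explained
#' variance; additionally compares a crude downstream prediction score (the
#' multiple correlation of hour-prior ICP on all transformed markers) before
#' and after polynomial detrending, to judge whether detrending would change
#' later analyses.
#'
#' @param data aligned tibble (uses `hour_index` as time since insertion).
#' @param orders polynomial orders to fit.
#' @param score_tolerance change in prediction score judged negligible.
#' @return list with `r_squared` (tibble variable x order) and
#'   `prediction_scores` (raw and per-order detrended multiple r, with a
#'   `detrending_matters` flag).
#' @export
trend_check <- function(data, orders = c(2, 3), score_tolerance = 0.02) {
  vars <- paste0(MD_MARKERS, "_t")
  h <- data$hour_index
  r2 <- lapply(vars, function(v) {
    y <- data[[v]]
    vapply(orders, function(k) {
      if (sd(y) == 0) return(0)
      summary(lm(y ~ poly(h, k)))$r.squared
    }, numeric(1))
  })
  r2_tbl <- tibble::tibble(variable = rep(vars, each = length(orders)),
                           order = rep(orders, length(vars)),
                           r_squared = unlist(r2))

  score <- function(X) {
    fit <- lm(data$icp_hour ~ ., data = as.data.frame(X))
    sqrt(summary(fit)$r.squared)
  }
  X_raw <- data[, vars]
  raw_score <- score(X_raw)
  detr <- vapply(orders, function(k) {
    Xd <- as.data.frame(lapply(X_raw, function(y) {
      if (sd(y) == 0) y else resid(lm(y ~ poly(h, k)))
    }))
    score(Xd)
  }, numeric(1))
  list(r_squared = r2_tbl,
       prediction_scores = tibble::tibble(
         design = c("raw", paste0("detrended_order_", orders)),
         score = c(raw_score, detr)),
       detrending_matters = any(abs(detr - raw_score) > score_tolerance))
}
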