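# Short-term and per-subject probes: differenced (delta) MD against
# pressures, per-subject z-normalized regressions, and per-subject mean
# regressions with Cook's-distance screening.

#' k-hour differences of an aligned frame
#'
#' Computes `x_t - x_{t-k}` for every marker, ratio and pressure column,
#' pairing only observations exactly `k` clock hours apart within a patient
#' (rows separated by a gap of any other length contribute no pair). The
#' pressure *level* at the later hour is carried alongside the differences
#' (`lag_level = TRUE` uses the earlier hour instead).
#'
#' @param data aligned tibble.
#' @param k difference order in hours (1 to 4).
#' @param lag_level pair differenced MD with the pressure level at `t - k`
#'   rather than at `t`?
#' @return tibble with `patient_id`, `hour_index` (of the later hour),
#'   `d_<var>` difference columns and `icp_level`, `cpp_level`.
#' @export
difference_series <- function(data, k, lag_level = FALSE) {
  if (!(k %in% 1:4)) stop("difference order k must be in 1..4")
  vars <- c(paste0(MD_MARKERS, "_t"), MD_RATIOS, "icp_hour", "cpp_hour")
  p <- .lag_pairs(data$patient_id, data$hour_index, k)[[1]]
  if (!length(p$ia)) {
    out <- tibble::tibble(patient_id = character(), hour_index = integer())
    for (v in vars) out[[paste0("d_", v)]] <- numeric(0)
    out$icp_level <- numeric(0)
    out$cpp_level <- numeric(0)
    return(out)
  }
  out <- tibble::tibble(patient_id = data$patient_id[p$ib],
                        hour_index = data$hour_index[p$ib])
  for (v in vars) {
    out[[paste0("d_", v)]] <- data[[v]][p$ib] - data[[v]][p$ia]
  }
  lvl <- if (lag_level) p$ia else p$ib
  out$icp_level <- data$icp_hour[lvl]
  out$cpp_level <- data$cpp_hour[lvl]
  attr(out, "k") <- k
  out
}

#' Per-subject z-normalization
#'
#' Centers and scales every requested column to mean 0 and SD 1 within each
#' patient, expressing values as deviations from the patient's own baseline.
#' Patients with fewer than `min_rows` rows or zero within-patient SD in any
#' column are dropped with a warning.
#'
#' @param data aligned tibble.
#' @param columns columns to normalize; defaults to transformed markers,
#'   ratios and both pressures.
#' @param min_rows minimum rows per patient.
#' @return the normalized tibble.
#' @export
normalize_per_subject <- function(data,
                                  columns = c(paste0(MD_MARKERS, "_t"),
                                              MD_RATIOS,
                                              "icp_hour", "cpp_hour"),
                                  min_rows = 3L) {
  counts <- table(data$patient_id)
  small <- names(counts)[counts < min_rows]
  zero_sd <- data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(columns), sd),
                     .groups = "drop")
  flat <- zero_sd$patient_id[apply(
    as.matrix(zero_sd[, columns]), 1, function(v) any(!is.finite(v) | v == 0))]
  drop <- union(small, flat)
  if (length(drop)) {
    warning("dropping ", length(drop),
            " patient(s) with too few rows or zero within-patient SD: ",
            paste(head(drop, 5), collapse = ", "))
    data <- data[!(data$patient_id %in% drop), ]
  }
  data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(columns),
                                ~ (.x - mean(.x)) / sd(.x))) |>
    dplyr::ungroup()
}

#' Per-patient whole-period means
#'
#' @param data aligned tibble.
#' @param columns columns to average.
#' @return one row per patient with the means, location and row count.
#' @export
subject_means <- function(data,
                          columns = c(paste0(MD_MARKERS, "_t"), MD_RATIOS,
                                      "icp_hour", "cpp_hour")) {
  data |>
    dplyr::group_by(.data$patient_id, .data$location) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(columns), mean),
                     n_hours = dplyr::n(), .groups = "drop")
}

#' Ordinary least-squares probe with Cook's-distance screening
#'
#' Fits `response ~ predictors` by OLS and reports coefficients, r-squared
#' and n. For `mode = "subject_means"` the input must hold one row per
#' patient (see [subject_means()]); significance is then tested against the
#' number of patients, and observations with Cook's distance above
#' `cooks_threshold` are excluded and the model refit (both fits reported).
#'
#' @param data input tibble.
#' @param response,predictors column names.
#' @param mode `"pooled"` (rows are samples) or `"subject_means"`.
#' @param cooks_threshold Cook's distance above which a row is flagged as
#'   unduly influential (default 1).
#' @return object of class `regression_report`: coefficient tibble,
#'   `r_squared`, `n`, `excluded` (patient ids and Cook's distances), and
#'   for screened fits the pre-exclusion counterpart under `$initial`.
#' @export
regress <- function(data, response, predictors,
                    mode = c("pooled", "subject_means"),
                    cooks_threshold = 1) {
  mode <- match.arg(mode)
  keep <- stats::complete.cases(data[, c(response, predictors)])
  data <- data[keep, ]
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 2) stop("too few rows (", n, ") for ", p, " predictors")
  if (mode == "subject_means" && anyDuplicated(data$patient_id)) {
    stop("subject_means mode expects one row per patient")
  }
  fml <- stats::reformulate(predictors, response)
  fit <- lm(fml, data = data)
  if (any(!is.finite(coef(fit)))) {
    stop("collinear predictors in OLS probe")
  }
  kappa_x <- kappa(stats::model.matrix(fit), exact = TRUE)
  if (kappa_x > 1e10) stop("ill-conditioned design (condition number ",
                           format(kappa_x, digits = 3), ")")
  report <- function(f, nn) {
    s <- summary(f)
    co <- s$coefficients
    structure(list(
      coefficients = tibble::tibble(
        term = rownames(co), estimate = unname(co[, 1]),
        std_error = unname(co[, 2]), t_value = unname(co[, 3]),
        p_value = unname(co[, 4])),
      r_squared = s$r.squared, n = nn,
      response = response, predictors = predictors, mode = mode,
      excluded = tibble::tibble(patient_id = character(),
                                cooks_distance = numeric())),
      class = "regression_report")
  }
  out <- report(fit, n)
  if (mode == "subject_means") {
    cd <- cooks.distance(fit)
    infl <- which(cd > cooks_threshold)
    if (length(infl)) {
      refit <- lm(fml, data = data[-infl, ])
      out2 <- report(refit, n - length(infl))
      out2$excluded <- tibble::tibble(
        patient_id = data$patient_id[infl],
        cooks_distance = unname(cd[infl]))
      out2$initial <- out
      out <- out2
    }
  }
  out
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("OLS (%s): %s ~ %s\n", x$mode, x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("r^2 = %.4f, n = %d\n", x$r_squared, x$n))
  if (nrow(x$excluded)) {
    cat("excluded (Cook's d > threshold):",
        paste(sprintf("%s (D = %.2f)", x$excluded$patient_id,
                      x$excluded$cooks_distance), collapse = ", "), "\n")
  }
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Grid of differenced short-term regressions
#'
#' For each difference order `k` in 1..4, each pressure response (ICP, CPP),
#' each pairing (pressure level at `t` or pressure difference over the same
#' `k` hours) and each stratum, runs univariate regressions of every
#' differenced marker/ratio plus one multivariate regression of all of them,
#' and collects r-squared with raw and Holm-adjusted p-values (smallest
#' coefficient p-value per design).
#'
#' @param data aligned tibble.
#' @param ks difference orders.
#' @param by_location analyse strata separately (default) as well as pooled?
#' @return tibble with one row per design.
#' @export
delta_report <- function(data, ks = 1:4, by_location = TRUE) {
  strata <- list(all = data)
  if (by_location) {
    for (loc in unique(data$location)) {
      strata[[loc]] <- data[data$location == loc, ]
    }
  }
  md_d <- paste0("d_", c(paste0(MD_MARKERS, "_t"), MD_RATIOS))
  rows <- list()
  for (sname in names(strata)) {
    for (k in ks) {
      dd <- difference_series(strata[[sname]], k)
      if (nrow(dd) < length(md_d) + 3) next
      for (resp_base in c("icp", "cpp")) {
        for (pairing in c("level", "difference")) {
          resp <- if (pairing == "level") {
            paste0(resp_base, "_level")
          } else paste0("d_", resp_base, "_hour")
          designs <- c(as.list(md_d), list(md_d))
          names(designs) <- c(md_d, "multivariate")
          for (dn in names(designs)) {
            rr <- tryCatch(
              regress(dd, resp, designs[[dn]], mode = "pooled"),
              error = function(e) NULL)
            if (is.null(rr)) next
            pv <- rr$coefficients$p_value[-1]
            rows[[length(rows) + 1]] <- tibble::tibble(
              stratum = sname, k = k, response = resp_base,
              pairing = pairing, design = dn,
              r_squared = rr$r_squared, n = rr$n, p_value = min(pv))
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    out <- out |>
      dplyr::group_by(.data$stratum, .data$response, .data$pairing) |>
      dplyr::mutate(p_holm = p.adjust(.data$p_value, method = "holm")) |>
      dplyr::ungroup()
  }
  out
}
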