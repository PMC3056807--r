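# Auto- and cross-correlograms on unbalanced hourly panels, with
# within-subject permutation nulls and subject-identity variance
# decomposition.
#
# Pairing always respects patient boundaries and true clock-hour offsets
# (gaps from dropped rows never create spurious adjacent pairs).

# Build, per lag 0..max_lag, integer indices (ia, ib) into `data` rows such
# that row ib is the same patient's observation exactly `lag` hours after
# row ia. Rows are identified by (patient_id, hour_index).
.lag_pairs <- function(patient_id, hour_index, lags) {
  key <- paste(patient_id, hour_index, sep = "\r")
  lookup <- seq_along(key)
  names(lookup) <- key
  lapply(lags, function(k) {
    target <- paste(patient_id, hour_index + k, sep = "\r")
    ib <- lookup[target]
    ia <- which(!is.na(ib))
    list(ia = ia, ib = unname(ib[ia]))
  })
}

.cor_or_na <- function(x, y, min_pairs = 2L) {
  if (length(x) < min_pairs) return(NA_real_)
  sx <- sd(x)
  sy <- sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  cor(x, y)
}

#' Autocorrelation function of a panel variable
#'
#' Correlation between a variable and itself `k` hours later, using only
#' within-patient pairs at exact clock-hour offsets. Two pooling modes:
#' `"pooled"` computes one Pearson correlation over all pairs from all
#' patients (pair components demeaned by the pooled per-lag means — the
#' low-bias default for short, strongly autocorrelated series);
#' `"per_patient"` computes a Pearson correlation per patient and combines
#' them by pair-count weighting. Constant series yield missing (not zero)
#' estimates.
#'
#' @param data tibble with `patient_id`, `hour_index` and the variable.
#' @param variable column name to autocorrelate.
#' @param max_lag maximum lag in hours.
#' @param pooling `"pooled"` or `"per_patient"`.
#' @param min_pairs lags with fewer pooled pairs are reported missing.
#' @return tibble with `lag`, `r`, `n_pairs`; `r` at lag 0 is exactly 1.
#' @export
panel_acf <- function(data, variable, max_lag = 30,
                      pooling = c("pooled", "per_patient"),
                      min_pairs = 30L) {
  pooling <- match.arg(pooling)
  x <- data[[variable]]
  lags <- 0:max_lag
  pairs <- .lag_pairs(data$patient_id, data$hour_index, lags)
  rows <- lapply(seq_along(lags), function(j) {
    p <- pairs[[j]]
    n <- length(p$ia)
    if (lags[j] == 0L) {
      return(tibble::tibble(lag = 0L, r = 1, n_pairs = n))
    }
    if (n < min_pairs) {
      return(tibble::tibble(lag = lags[j], r = NA_real_, n_pairs = n))
    }
    r <- if (pooling == "pooled") {
      .cor_or_na(x[p$ia], x[p$ib])
    } else {
      pid <- data$patient_id[p$ia]
      rs <- vapply(split(seq_len(n), pid), function(idx) {
        c(.cor_or_na(x[p$ia[idx]], x[p$ib[idx]], min_pairs = 3L),
          length(idx))
      }, numeric(2))
      ok <- !is.na(rs[1, ])
      if (!any(ok)) NA_real_ else weighted.mean(rs[1, ok], rs[2, ok])
    }
    tibble::tibble(lag = lags[j], r = r, n_pairs = n)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "variable") <- variable
  attr(out, "pooling") <- pooling
  out
}

#' Lagged cross-correlation of an MD variable against a pressure variable
#'
#' At lag `l`, correlates the MD value at hour `t` with the pressure at hour
#' `t + l` (within patients only); positive lags mean the pressure is
#' sampled *after* the MD vial. The `"pooled"` mode correlates all
#' subject-hours jointly (the mode in which between-subject mean structure
#' is visible); `"per_patient"` averages per-patient correlations with
#' pair-count weights.
#'
#' @param data aligned tibble with `patient_id`, `hour_index` and both
#'   variables.
#' @param md_variable,pressure_variable column names.
#' @param max_lag lags run from `-max_lag` to `+max_lag` hours.
#' @inheritParams panel_acf
#' @return tibble of class `correlogram` with `lag`, `r`, `n_pairs`.
#' @export
panel_ccf <- function(data, md_variable, pressure_variable, max_lag = 35,
                      pooling = c("pooled", "per_patient"),
                      min_pairs = 30L) {
  pooling <- match.arg(pooling)
  idx <- .ccf_index(data, max_lag)
  out <- .ccf_from_index(data[[md_variable]], data[[pressure_variable]],
                         data$patient_id, idx, pooling, min_pairs)
  attr(out, "pair") <- c(md_variable, pressure_variable)
  attr(out, "pooling") <- pooling
  class(out) <- c("correlogram", class(out))
  out
}

# Precomputed pair indices for all lags -max_lag..max_lag; `g` holds
# integer patient codes per pair for the grouped (per-patient) mode.
.ccf_index <- function(data, max_lag) {
  lags <- (-max_lag):max_lag
  pairs <- .lag_pairs(data$patient_id, data$hour_index, lags)
  pid_codes <- as.integer(factor(data$patient_id))
  pairs <- lapply(pairs, function(p) {
    p$g <- pid_codes[p$ia]
    p
  })
  list(lags = lags, pairs = pairs)
}

# Correlation over one lag's pairs: pooled Pearson, or pair-count-weighted
# per-patient Pearson (grouped sums via rowsum; patients contributing fewer
# than 3 pairs or a constant series are skipped).
.lag_r <- function(x, y, g, pooling) {
  if (pooling == "pooled") return(.cor_or_na(x, y))
  M <- rowsum(cbind(1, x, y, x * y, x * x, y * y), g)
  n <- M[, 1]
  num <- M[, 4] - M[, 2] * M[, 3] / n
  vx <- M[, 5] - M[, 2]^2 / n
  vy <- M[, 6] - M[, 3]^2 / n
  ok <- n >= 3 & vx > 1e-12 & vy > 1e-12
  if (!any(ok)) return(NA_real_)
  weighted.mean(num[ok] / sqrt(vx[ok] * vy[ok]), n[ok])
}

.ccf_from_index <- function(md, pres, patient_id, idx, pooling = "pooled",
                            min_pairs = 30L) {
  rows <- lapply(seq_along(idx$lags), function(j) {
    p <- idx$pairs[[j]]
    n <- length(p$ia)
    if (n < min_pairs) {
      return(tibble::tibble(lag = idx$lags[j], r = NA_real_, n_pairs = n))
    }
    tibble::tibble(lag = idx$lags[j],
                   r = .lag_r(md[p$ia], pres[p$ib], p$g, pooling),
                   n_pairs = n)
  })
  dplyr::bind_rows(rows)
}

# Permute positions within each patient; returns a permutation of seq_len(n).
.within_patient_perm <- function(patient_id) {
  idx <- seq_along(patient_id)
  unsplit(lapply(split(idx, patient_id),
                 function(v) v[sample.int(length(v))]), patient_id)
}

#' Cross-correlogram with a within-subject permutation null
#'
#' Builds the Monte-Carlo reference band for the pooled lagged MD-pressure
#' correlations by repeatedly scrambling the order of each patient's MD
#' values while keeping the pressure series fixed. Scrambling destroys the
#' temporal alignment within patients but preserves every patient's marginal
#' MD distribution (and hence the between-subject mean structure): observed
#' correlations inside the band carry no information beyond subject means.
#' A full-scramble control (permuting MD across all patients jointly) is
#' computed alongside and collapses all structure to near zero.
#'
#' @inheritParams panel_ccf
#' @param B number of permutation replicates (>= 100).
#' @param level coverage of the pointwise percentile band.
#' @param seed RNG seed for the permutations.
#' @return tibble of class `correlogram` with columns `lag`, `r` (observed),
#'   `lo`, `hi` (within-subject permutation band), `scramble_r` (mean
#'   full-scramble correlation), `scramble_lo`, `scramble_hi`, `n_pairs`;
#'   attributes record the pooling mode, `B`, `level` and `seed`.
#' @export
permute_within_subjects <- function(data, md_variable, pressure_variable,
                                    max_lag = 35, B = 1000, level = 0.95,
                                    pooling = c("pooled", "per_patient"),
                                    min_pairs = 30L, seed = 1L) {
  pooling <- match.arg(pooling)
  if (B < 100) stop("B must be >= 100 for a stable percentile band")
  if (B * (1 - level) / 2 < 1) {
    stop("B too small for the requested band level")
  }
  idx <- .ccf_index(data, max_lag)
  md <- data[[md_variable]]
  pres <- data[[pressure_variable]]
  pid <- data$patient_id
  observed <- .ccf_from_index(md, pres, pid, idx, pooling, min_pairs)

  set.seed(seed)
  L <- length(idx$lags)
  within_mat <- matrix(NA_real_, B, L)
  full_mat <- matrix(NA_real_, B, L)
  n <- length(md)
  for (b in seq_len(B)) {
    mw <- md[.within_patient_perm(pid)]
    mf <- md[sample.int(n)]
    for (j in seq_len(L)) {
      p <- idx$pairs[[j]]
      if (length(p$ia) >= min_pairs) {
        within_mat[b, j] <- .lag_r(mw[p$ia], pres[p$ib], p$g, pooling)
        full_mat[b, j] <- .lag_r(mf[p$ia], pres[p$ib], p$g, pooling)
      }
    }
  }
  alpha <- (1 - level) / 2
  qs <- function(m, p) apply(m, 2, quantile, probs = p, na.rm = TRUE,
                             names = FALSE)
  out <- observed
  out$lo <- qs(within_mat, alpha)
  out$hi <- qs(within_mat, 1 - alpha)
  out$scramble_r <- colMeans(full_mat)
  out$scramble_lo <- qs(full_mat, alpha)
  out$scramble_hi <- qs(full_mat, 1 - alpha)
  attr(out, "pair") <- c(md_variable, pressure_variable)
  attr(out, "pooling") <- pooling
  attr(out, "B") <- B
  attr(out, "level") <- level
  attr(out, "seed") <- seed
  class(out) <- c("correlogram", class(out))
  out
}

#' Variance in a panel variable explained by subject identity
#'
#' r-squared of a least-squares regression of each requested variable on
#' subject-indicator variables, i.e. `1 - SS_within / SS_total`. For long
#' series this estimates the intraclass correlation
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2)`.
#'
#' @param data tibble with `patient_id` and the variables.
#' @param variables column names to decompose.
#' @return tibble with `variable`, `r_squared`, `n_patients`, `n_samples`.
#' @export
identity_variance <- function(data, variables) {
  if (length(unique(data$patient_id)) < 2) {
    stop("identity variance needs at least 2 patients")
  }
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    ok <- !is.na(x)
    x <- x[ok]
    g <- data$patient_id[ok]
    gm <- ave(x, g)
    ss_tot <- sum((x - mean(x))^2)
    r2 <- if (ss_tot == 0) NA_real_ else 1 - sum((x - gm)^2) / ss_tot
    tibble::tibble(variable = v, r_squared = r2,
                   n_patients = length(unique(g)), n_samples = length(x))
  })
  dplyr::bind_rows(rows)
}
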