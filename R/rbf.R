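# Radial-basis-function network regression with leave-one-subject-out
# cross-validation and permuted-data controls.
#
# Training is deterministic-classical: k-means centers on standardized
# predictors, per-center widths from the two nearest other centers, ridge
# regularized linear output layer with an unpenalized bias.

#' Fit a Gaussian radial-basis-function network
#'
#' @param X numeric matrix (rows = training samples) of predictors.
#' @param y numeric response.
#' @param n_nodes number of Gaussian basis centers (>= 1, <= nrow(X)).
#' @param ridge ridge penalty on output weights (bias unpenalized).
#' @param seed RNG seed for the k-means center placement.
#' @return object of class `rbf_model`.
#' @export
fit_rbf <- function(X, y, n_nodes, ridge = 1e-2, seed = 1L) {
  X <- as.matrix(X)
  if (n_nodes < 1) stop("n_nodes must be >= 1")
  if (n_nodes > nrow(X)) {
    stop("n_nodes (", n_nodes, ") exceeds training rows (", nrow(X), ")")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)

  set.seed(seed)
  uniq <- unique(Z)
  k <- min(n_nodes, nrow(uniq))
  centers <- if (k == 1) {
    matrix(colMeans(Z), 1)
  } else {
    km <- suppressWarnings(kmeans(Z, centers = k, nstart = 5, iter.max = 50))
    km$centers
  }

  if (k >= 3) {
    D <- as.matrix(dist(centers))
    diag(D) <- Inf
    widths <- apply(D, 1, function(d) mean(sort(d)[1:2]))
  } else if (k == 2) {
    widths <- rep(as.numeric(dist(centers)), 2)
  } else {
    # single node: spread of the data around the center
    widths <- sqrt(mean(rowSums(
      sweep(Z, 2, centers[1, ])^2)) + .Machine$double.eps)
  }
  widths <- pmax(widths, 1e-6)

  A <- .rbf_activations(Z, centers, widths)
  Ab <- cbind(1, A)
  pen <- diag(c(0, rep(ridge, ncol(A))))
  w <- solve(crossprod(Ab) + pen, crossprod(Ab, y))

  structure(list(centers = centers, widths = widths,
                 weights = w[-1, 1], bias = w[1, 1],
                 n_nodes = k, ridge = ridge,
                 x_center = ctr, x_scale = scl, seed = seed),
            class = "rbf_model")
}

.rbf_activations <- function(Z, centers, widths) {
  d2 <- outer(rowSums(Z^2), rowSums(centers^2), "+") -
    2 * Z %*% t(centers)
  exp(-pmax(d2, 0) / (2 * matrix(widths^2, nrow(Z), length(widths),
                                 byrow = TRUE)))
}

#' @export
predict.rbf_model <- function(object, newdata, ...) {
  Z <- scale(as.matrix(newdata), center = object$x_center,
             scale = object$x_scale)
  A <- .rbf_activations(Z, object$centers, object$widths)
  as.numeric(object$bias + A %*% object$weights)
}

.default_rbf_predictors <- function() {
  c(paste0(MD_MARKERS, "_t"), MD_RATIOS)
}

# Grouped k-fold assignment of patients.
.patient_folds <- function(ids, k) {
  k <- min(k, length(ids))
  split(ids, rep_len(seq_len(k), length(ids))[sample.int(length(ids))])
}

#' Leave-one-subject-out cross-validated RBF prediction
#'
#' Outer loop: every patient is held out once; all their rows are excluded
#' from fitting *and* from model selection. Inner loop: the node count is
#' chosen by grouped k-fold cross-validation over the remaining patients
#' only. Predictions for held-out rows are pooled into a single Pearson
#' correlation of true vs. predicted response; the procedure is repeated
#' with `repeats` different seeds and the spread reported.
#'
#' @param data aligned tibble with `patient_id`, predictors and the response.
#' @param response response column (e.g. `"icp_hour"`).
#' @param predictors predictor columns; defaults to the transformed markers
#'   plus both ratios.
#' @param node_grid candidate node counts for inner selection.
#' @param repeats number of repeated CV runs (different seeds).
#' @param inner_folds grouped folds for inner model selection.
#' @param ridge output-layer ridge penalty.
#' @param permute `"none"` (observed), `"within"` (scramble each patient's
#'   predictor rows against their own response hours) or `"across"`
#'   (scramble rows over the whole data set).
#' @param seed base RNG seed; repeat `j` uses `seed + j - 1`.
#' @return object of class `cv_prediction`: pooled `r` (mean over repeats),
#'   `r_sd`, per-repeat values, per-patient held-out predictions from the
#'   first repeat, and the configuration.
#' @export
loso_cv <- function(data, response, predictors = .default_rbf_predictors(),
                    node_grid = c(2, 4, 8, 16), repeats = 10,
                    inner_folds = 5, ridge = 1e-2,
                    permute = c("none", "within", "across"), seed = 1L) {
  permute <- match.arg(permute)
  if (!length(node_grid)) stop("node_grid is empty")
  keep <- stats::complete.cases(data[, c(response, predictors)])
  data <- data[keep, ]
  ids <- unique(data$patient_id)
  if (length(ids) < 5) stop("loso_cv needs at least 5 patients")

  run_once <- function(run_seed) {
    set.seed(run_seed)
    d <- data
    if (permute == "within") {
      perm <- .within_patient_perm(d$patient_id)
      d[, predictors] <- d[perm, predictors]
    } else if (permute == "across") {
      d[, predictors] <- d[sample.int(nrow(d)), predictors]
    }
    X <- as.matrix(d[, predictors])
    y <- d[[response]]
    pid <- d$patient_id

    preds <- rep(NA_real_, nrow(d))
    for (hold in ids) {
      tr <- pid != hold
      inner_ids <- setdiff(ids, hold)
      folds <- .patient_folds(inner_ids, inner_folds)
      mse <- vapply(node_grid, function(nn) {
        errs <- vapply(folds, function(fold) {
          fit_tr <- !(pid %in% c(fold, hold))
          fit_va <- pid %in% fold
          if (sum(fit_tr) <= nn) return(NA_real_)
          m <- fit_rbf(X[fit_tr, , drop = FALSE], y[fit_tr], nn,
                       ridge = ridge, seed = run_seed)
          mean((y[fit_va] - predict(m, X[fit_va, , drop = FALSE]))^2)
        }, numeric(1))
        mean(errs, na.rm = TRUE)
      }, numeric(1))
      mse[!is.finite(mse)] <- Inf
      nn_best <- node_grid[which.min(mse)]
      if (!length(nn_best) || !is.finite(min(mse))) nn_best <- min(node_grid)
      m <- fit_rbf(X[tr, , drop = FALSE], y[tr], nn_best,
                   ridge = ridge, seed = run_seed)
      preds[!tr] <- predict(m, X[!tr, , drop = FALSE])
    }
    list(r = .cor_or_na(y, preds), preds = preds, truth = y, pid = pid)
  }

  runs <- lapply(seq_len(repeats), function(j) run_once(seed + j - 1L))
  rs <- vapply(runs, `[[`, numeric(1), "r")
  structure(list(
    r = mean(rs), r_sd = sd(rs), r_runs = rs,
    predictions = tibble::tibble(patient_id = runs[[1]]$pid,
                                 truth = runs[[1]]$truth,
                                 predicted = runs[[1]]$preds),
    response = response, predictors = predictors, permute = permute,
    node_grid = node_grid, repeats = repeats, seed = seed),
    class = "cv_prediction")
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf(
    "LOSO CV (%s, permute = %s): r = %.3f +/- %.3f over %d repeats\n",
    x$response, x$permute, x$r,
    if (is.na(x$r_sd)) 0 else x$r_sd, x$repeats))
  invisible(x)
}

#' Permuted-data control for the LOSO RBF prediction
#'
#' Runs the identical cross-validation after permuting each patient's
#' predictor rows against their own response hours: temporal alignment is
#' destroyed while every patient keeps their own predictor distribution.
#' Predictive skill that survives this control rests on subject means, not
#' on hour-to-hour coupling.
#'
#' @inheritParams loso_cv
#' @return list with `observed` and `permuted` `cv_prediction`s and the
#'   difference in pooled correlation.
#' @export
permuted_control <- function(data, response,
                             predictors = .default_rbf_predictors(),
                             node_grid = c(2, 4, 8, 16), repeats = 10,
                             inner_folds = 5, ridge = 1e-2, seed = 1L) {
  obs <- loso_cv(data, response, predictors, node_grid, repeats,
                 inner_folds, ridge, permute = "none", seed = seed)
  per <- loso_cv(data, response, predictors, node_grid, repeats,
                 inner_folds, ridge, permute = "within", seed = seed)
  list(observed = obs, permuted = per, r_difference = obs$r - per$r)
}

#' Search over response representations for per-patient prediction
#'
#' Compares alternative per-patient summaries of the pressure stream (hourly
#' mean over the monitoring period; hours above/below each cutoff;
#' percentage of monitored hours above/below each cutoff) as targets of a
#' leave-one-patient-out linear prediction from per-patient mean transformed
#' MD predictors, and ranks them by cross-validated predictive correlation.
#' Representations with (near-)zero variance are flagged and skipped.
#'
#' @param data aligned tibble.
#' @param response `"icp"` or `"cpp"`.
#' @param cutoffs cutoff grid in mmHg; defaults to 15/20/25/30 for ICP and
#'   40/50/60/70/80/90 for CPP.
#' @param predictors per-row predictor columns averaged per patient.
#' @return tibble ranked by |r| with representation, r and a degenerate
#'   flag.
#' @export
representation_search <- function(data, response = c("icp", "cpp"),
                                  cutoffs = NULL,
                                  predictors = .default_rbf_predictors()) {
  response <- match.arg(response)
  if (is.null(cutoffs)) {
    cutoffs <- if (response == "icp") c(15, 20, 25, 30) else
      c(40, 50, 60, 70, 80, 90)
  }
  pcol <- paste0(response, "_hour")
  per_pat <- data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(predictors), mean),
      .p_mean = mean(.data[[pcol]]),
      .n_hours = dplyr::n(),
      .p_vals = list(.data[[pcol]]), .groups = "drop")

  reps <- list(hourly_mean = per_pat$.p_mean)
  for (co in cutoffs) {
    above <- vapply(per_pat$.p_vals, function(v) sum(v > co), numeric(1))
    reps[[sprintf("hours_above_%g", co)]] <- above
    reps[[sprintf("hours_below_%g", co)]] <- per_pat$.n_hours - above
    reps[[sprintf("pct_above_%g", co)]] <- 100 * above / per_pat$.n_hours
    reps[[sprintf("pct_below_%g", co)]] <-
      100 * (1 - above / per_pat$.n_hours)
  }

  Xp <- as.matrix(per_pat[, predictors])
  rows <- lapply(names(reps), function(nm) {
    yv <- reps[[nm]]
    if (sd(yv) < 1e-12) {
      return(tibble::tibble(representation = nm, r = NA_real_,
                            degenerate = TRUE))
    }
    tibble::tibble(representation = nm, r = .loo_linear_r(Xp, yv),
                   degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-abs(out$r), na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  out
}

# Leave-one-out cross-validated correlation of an OLS prediction;
# closed-form via hat-matrix leverages (PRESS residuals).
.loo_linear_r <- function(X, y) {
  Xb <- cbind(1, X)
  qx <- qr(Xb)
  if (qx$rank < ncol(Xb)) {
    Xb <- Xb[, seq_len(qx$rank), drop = FALSE]
    qx <- qr(Xb)
  }
  H <- Xb %*% qr.solve(crossprod(Xb), t(Xb))
  fitted <- as.numeric(H %*% y)
  h <- diag(H)
  loo_pred <- y - (y - fitted) / pmax(1 - h, 1e-8)
  .cor_or_na(y, loo_pred)
}
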