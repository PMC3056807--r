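# Synthetic cohort generator.
#
# Emulates the second-order statistical structure of a neurocritical-care
# multimodal-monitoring cohort: hourly microdialysis vials with strong
# within-patient autocorrelation and large between-patient variance, minute
# level ICP/MAP streams around clinical targets, weak configurable MD<->
# pressure coupling, and ordinal GOS outcomes driven by mean pressures.

.BASE_TIME <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

#' Configuration for the synthetic cohort generator
#'
#' All marker-indexed arguments are named vectors over
#' `c("glucose", "lactate", "pyruvate", "glycerol")` and live on the modeling
#' scale (square root for glucose/lactate/pyruvate in mM/l or uM/l, log10 for
#' glycerol in uM/l). Defaults emulate a ~90-patient traumatic-brain-injury
#' cohort with a mean of 84 complete hourly samples per patient, adjacent-hour
#' within-subject marker correlation in the 0.77-0.83 range, subject identity
#' explaining roughly 52-75% of marker variance, weak pressure coupling, ICP
#' centred near the <= 20 mmHg clinical target and CPP near 60-70 mmHg.
#'
#' @param n_patients number of patients.
#' @param hours_mean expected complete hourly MD samples per patient.
#' @param hours_dispersion negative-binomial size parameter for series length.
#' @param md_alpha marker intercepts on the modeling scale.
#' @param md_alpha_peri_shift additive intercept shift for pericontusional
#'   catheters.
#' @param md_phi,md_theta ARMA(1,1) coefficients of the within-patient marker
#'   deviation process (|phi| < 1, |theta| < 1).
#' @param md_subject_sd between-patient SD of the marker random intercept.
#' @param md_resid_sd innovation SD of the within-patient ARMA process.
#' @param coupling_icp,coupling_cpp per-location lists of named coefficient
#'   vectors: effect of hour-prior mean ICP / CPP (mmHg, centred at the
#'   population mean) on each transformed marker.
#' @param coupling_mode `"hourly"` couples markers to the realized hour-prior
#'   pressure means; `"subject_mean"` couples them to the patient's long-run
#'   pressure level only (a means-only cohort with no within-subject coupling).
#' @param icp_mean_sd length-2 vector: population mean and SD of the patient
#'   ICP level (mmHg), truncated at 0.
#' @param icp_phi AR(1) coefficient of minute-level ICP deviations.
#' @param icp_sd stationary SD of minute-level ICP deviations (mmHg).
#' @param map_mean_sd,map_phi,map_sd same for mean arterial pressure.
#' @param pressure_dt pressure sampling interval in minutes (1 or 2).
#' @param frac_pericontusional proportion of pericontusional catheters.
#' @param gos_coefficients named vector `c(icp =, cpp =)`: ordinal-logistic
#'   weights of centred mean ICP and CPP on GOS (latent scale).
#' @param gos_thresholds four increasing cutpoints of the cumulative-logit
#'   GOS model.
#' @param followup_loss_rate probability a patient has only a discharge GOS.
#' @param missing_rate marker-wise probability that a vial's assay is missing.
#' @param transfer_minutes catheter membrane-to-vial transfer time (min);
#'   vial times are stamped this long after the membrane sampling window.
#' @param seed integer RNG seed; identical seed + config give an identical
#'   cohort.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 90,
                          hours_mean = 84,
                          hours_dispersion = 8,
                          md_alpha = c(glucose = 1.40, lactate = 2.20,
                                       pyruvate = 13.0, glycerol = 2.35),
                          md_alpha_peri_shift = c(glucose = 0, lactate = 0.15,
                                                  pyruvate = 0, glycerol = 0),
                          md_phi = c(glucose = 0.77, lactate = 0.81,
                                     pyruvate = 0.79, glycerol = 0.83),
                          md_theta = c(glucose = 0, lactate = 0,
                                       pyruvate = 0, glycerol = 0),
                          md_subject_sd = c(glucose = 0.36, lactate = 0.68,
                                            pyruvate = 3.2, glycerol = 0.39),
                          md_resid_sd = c(glucose = 0.22, lactate = 0.23,
                                          pyruvate = 1.5, glycerol = 0.17),
                          coupling_icp = NULL,
                          coupling_cpp = NULL,
                          coupling_mode = c("hourly", "subject_mean"),
                          icp_mean_sd = c(14, 4),
                          icp_phi = 0.8,
                          icp_sd = 3,
                          map_mean_sd = c(80, 6),
                          map_phi = 0.8,
                          map_sd = 4,
                          pressure_dt = 1,
                          frac_pericontusional = 64 / 90,
                          gos_coefficients = c(icp = -0.30, cpp = 0.08),
                          gos_thresholds = c(-1.73, -1.59, -0.28, 1.10),
                          followup_loss_rate = 0.03,
                          missing_rate = 0.05,
                          transfer_minutes = 17,
                          seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  zero <- setNames(numeric(4), MD_MARKERS)
  default_icp <- list(
    pericontusional = c(glucose = -0.010, lactate = 0.006,
                        pyruvate = 0, glycerol = 0.004),
    nonpericontusional = c(glucose = -0.010, lactate = 0.006,
                           pyruvate = 0, glycerol = 0.006))
  default_cpp <- list(
    pericontusional = c(glucose = 0.006, lactate = -0.004,
                        pyruvate = 0, glycerol = 0),
    nonpericontusional = zero)
  if (is.null(coupling_icp)) coupling_icp <- default_icp
  if (is.null(coupling_cpp)) coupling_cpp <- default_cpp
  coupling_icp <- .as_coupling(coupling_icp)
  coupling_cpp <- .as_coupling(coupling_cpp)

  cfg <- list(
    n_patients = as.integer(n_patients), hours_mean = hours_mean,
    hours_dispersion = hours_dispersion,
    md_alpha = .marker_vec(md_alpha),
    md_alpha_peri_shift = .marker_vec(md_alpha_peri_shift),
    md_phi = .marker_vec(md_phi), md_theta = .marker_vec(md_theta),
    md_subject_sd = .marker_vec(md_subject_sd),
    md_resid_sd = .marker_vec(md_resid_sd),
    coupling_icp = coupling_icp, coupling_cpp = coupling_cpp,
    coupling_mode = coupling_mode,
    icp_mean_sd = icp_mean_sd, icp_phi = icp_phi, icp_sd = icp_sd,
    map_mean_sd = map_mean_sd, map_phi = map_phi, map_sd = map_sd,
    pressure_dt = pressure_dt,
    frac_pericontusional = frac_pericontusional,
    gos_coefficients = gos_coefficients, gos_thresholds = gos_thresholds,
    followup_loss_rate = followup_loss_rate,
    missing_rate = missing_rate,
    transfer_minutes = transfer_minutes,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

.marker_vec <- function(x) {
  if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 4), MD_MARKERS)
  if (!all(MD_MARKERS %in% names(x))) {
    stop("marker-indexed config vectors need names ",
         paste(MD_MARKERS, collapse = ", "))
  }
  x[MD_MARKERS]
}

.as_coupling <- function(x) {
  if (!is.list(x)) x <- list(pericontusional = x, nonpericontusional = x)
  lapply(x[MD_LOCATIONS], .marker_vec)
}

#' Validate a cohort configuration
#'
#' Checks stationarity of every ARMA coefficient, positivity of SDs, and
#' range constraints; errors with an explicit message otherwise.
#'
#' @param config a `cohort_config`.
#' @return the config, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients < 0) stop("n_patients must be >= 0")
  if (any(abs(config$md_phi) >= 1)) {
    stop("non-stationary marker AR coefficient: all |phi| must be < 1")
  }
  if (any(abs(config$md_theta) >= 1)) {
    stop("non-invertible marker MA coefficient: all |theta| must be < 1")
  }
  if (abs(config$icp_phi) >= 1 || abs(config$map_phi) >= 1) {
    stop("non-stationary pressure AR coefficient: |phi| must be < 1")
  }
  sds <- c(config$md_subject_sd, config$md_resid_sd,
           config$icp_sd, config$map_sd,
           config$icp_mean_sd[2], config$map_mean_sd[2])
  if (any(sds < 0)) stop("negative SD in cohort config")
  if (config$frac_pericontusional < 0 || config$frac_pericontusional > 1) {
    stop("frac_pericontusional must be in [0, 1]")
  }
  if (config$missing_rate < 0 || config$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (is.unsorted(config$gos_thresholds, strictly = TRUE)) {
    stop("gos_thresholds must be strictly increasing")
  }
  if (!(60 %% config$pressure_dt == 0)) {
    stop("pressure_dt must divide 60 minutes")
  }
  invisible(config)
}

#' Between-subject SD achieving a target intraclass correlation
#'
#' Given the within-subject ARMA(1,1) innovation SD and coefficients, returns
#' the subject-level SD such that
#' ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2), where sigma_w is the stationary
#' SD of the ARMA process.
#'
#' @param icc target intraclass correlation in (0, 1).
#' @param resid_sd innovation SD.
#' @param phi,theta ARMA(1,1) coefficients.
#' @return the between-subject SD.
#' @export
subject_sd_for_icc <- function(icc, resid_sd, phi, theta = 0) {
  stopifnot(icc > 0, icc < 1, abs(phi) < 1)
  var_w <- resid_sd^2 * (1 + 2 * phi * theta + theta^2) / (1 - phi^2)
  sqrt(var_w * icc / (1 - icc))
}

# Stationary ARMA(1,1) path: s_t = phi s_{t-1} + e_t + theta e_{t-1}.
.sim_arma11 <- function(n, phi, theta, innov_sd, burn = 100L) {
  if (n == 0L) return(numeric(0))
  e <- rnorm(n + burn, sd = innov_sd)
  u <- e + theta * c(0, e[-(n + burn)])
  s <- as.numeric(stats::filter(u, phi, method = "recursive"))
  s[(burn + 1):(burn + n)]
}

# AR(1) path with given stationary SD (not innovation SD).
.sim_ar1 <- function(n, phi, stat_sd, burn = 200L) {
  .sim_arma11(n, phi, 0, stat_sd * sqrt(1 - phi^2), burn = burn)
}

.draw_truncnorm_pos <- function(mean, sd) {
  for (i in 1:1000) {
    x <- rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
  stop("failed to draw a positive pressure level")
}

#' Simulate a synthetic monitoring cohort
#'
#' Generates per-patient minute-level ICP and MAP streams (CPP = MAP - ICP),
#' hourly microdialysis vials for the four markers on their modeling scales
#' (marker = intercept + subject effect + pressure coupling + stationary
#' ARMA(1,1) deviation, then back-transformed to raw units), and GOS scores
#' drawn from a cumulative-logit model on the patient's mean ICP and CPP.
#' Vial assays are thinned marker-wise at `missing_rate`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `md_cohort`: a list of tibbles `patients`
#'   (patient_id, location, gos_discharge, gos_3to6m, gos_1y), `md`
#'   (patient_id, vial_time, marker, value; missing assays are absent rows)
#'   and `pressures` (patient_id, timestamp, variable in ICP/MAP, value),
#'   with the config attached as an attribute.
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(max(n, 0)))

  # patient-level draws from the global stream, then a deterministic
  # per-patient substream seed for the time series
  n_hours <- if (is.infinite(config$hours_dispersion)) {
    rep(as.integer(round(config$hours_mean)), n)
  } else {
    pmax(2L, rnbinom(n, mu = config$hours_mean,
                     size = config$hours_dispersion))
  }
  location <- ifelse(runif(n) < config$frac_pericontusional,
                     "pericontusional", "nonpericontusional")
  mu_icp <- vapply(seq_len(n), function(i)
    .draw_truncnorm_pos(config$icp_mean_sd[1], config$icp_mean_sd[2]),
    numeric(1))
  mu_map <- rnorm(n, config$map_mean_sd[1], config$map_mean_sd[2])
  a_subj <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(NULL, MD_MARKERS)) %*%
    diag(config$md_subject_sd)
  colnames(a_subj) <- MD_MARKERS
  lost <- runif(n) < config$followup_loss_rate
  pat_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))

  cpp_pop_mean <- config$map_mean_sd[1] - config$icp_mean_sd[1]
  md_list <- vector("list", n)
  pres_list <- vector("list", n)
  pat_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(pat_seeds[i])
    nh <- n_hours[i]
    dt <- config$pressure_dt
    per_hour <- 60 %/% dt
    n_min <- nh * per_hour
    icp <- mu_icp[i] + .sim_ar1(n_min, config$icp_phi, config$icp_sd)
    map <- mu_map[i] + .sim_ar1(n_min, config$map_phi, config$map_sd)
    icp <- pmax(icp, 0)
    minute <- seq_len(n_min) * dt
    icp_hr <- colMeans(matrix(icp, nrow = per_hour))
    cpp_hr <- colMeans(matrix(map - icp, nrow = per_hour))

    if (config$coupling_mode == "subject_mean") {
      icp_drive <- rep(mu_icp[i], nh)
      cpp_drive <- rep(mu_map[i] - mu_icp[i], nh)
    } else {
      icp_drive <- icp_hr
      cpp_drive <- cpp_hr
    }

    bi <- config$coupling_icp[[location[i]]]
    bc <- config$coupling_cpp[[location[i]]]
    shift <- if (location[i] == "pericontusional") {
      config$md_alpha_peri_shift
    } else setNames(numeric(4), MD_MARKERS)

    vals <- sapply(MD_MARKERS, function(mk) {
      m <- config$md_alpha[mk] + shift[mk] + a_subj[i, mk] +
        bi[mk] * (icp_drive - config$icp_mean_sd[1]) +
        bc[mk] * (cpp_drive - cpp_pop_mean) +
        .sim_arma11(nh, config$md_phi[mk], config$md_theta[mk],
                    config$md_resid_sd[mk])
      if (mk == "glycerol") m else pmax(m, 0.05)
    })
    vals <- matrix(vals, nrow = nh, dimnames = list(NULL, MD_MARKERS))
    raw <- sapply(MD_MARKERS, function(mk) md_backtransform(vals[, mk], mk))
    raw <- matrix(raw, nrow = nh, dimnames = list(NULL, MD_MARKERS))

    vial_time <- .BASE_TIME + 60 * (seq_len(nh) * 60 + config$transfer_minutes)
    md_i <- tibble::tibble(
      patient_id = ids[i],
      vial_time = rep(vial_time, each = 4L),
      marker = rep(MD_MARKERS, times = nh),
      value = as.vector(t(raw)))
    keep <- runif(nrow(md_i)) >= config$missing_rate
    md_list[[i]] <- md_i[keep, ]

    pres_list[[i]] <- tibble::tibble(
      patient_id = ids[i],
      timestamp = rep(.BASE_TIME + 60 * minute, 2L),
      variable = rep(c("ICP", "MAP"), each = n_min),
      value = c(icp, map))

    # GOS: latent logistic on centred mean pressures; best score over epochs
    eta <- config$gos_coefficients["icp"] * (mean(icp_hr) - config$icp_mean_sd[1]) +
      config$gos_coefficients["cpp"] * (mean(cpp_hr) - cpp_pop_mean)
    latent <- eta + rlogis(1)
    gos_1y <- 1L + sum(latent > config$gos_thresholds)
    if (gos_1y == 1L) {
      gos_dis <- 1L
      gos_mid <- 1L
    } else {
      gos_dis <- max(1L, gos_1y - sample(0:2, 1, prob = c(0.3, 0.5, 0.2)))
      mid_range <- gos_dis:gos_1y
      gos_mid <- mid_range[sample.int(length(mid_range), 1)]
    }
    pat_rows[[i]] <- tibble::tibble(
      patient_id = ids[i], location = location[i],
      gos_discharge = gos_dis,
      gos_3to6m = if (lost[i]) NA_integer_ else gos_mid,
      gos_1y = if (lost[i]) NA_integer_ else gos_1y)
  }

  cohort <- list(
    patients = dplyr::bind_rows(pat_rows) %||% .empty_patients(),
    md = dplyr::bind_rows(md_list) %||% .empty_md(),
    pressures = dplyr::bind_rows(pres_list) %||% .empty_pressures())
  if (n == 0L) {
    cohort <- list(patients = .empty_patients(), md = .empty_md(),
                   pressures = .empty_pressures())
  }
  attr(cohort, "config") <- config
  class(cohort) <- "md_cohort"
  cohort
}

`%||%` <- function(a, b) if (is.null(a) || (is.data.frame(a) && !nrow(a))) b else a

.empty_patients <- function() {
  tibble::tibble(patient_id = character(), location = character(),
                 gos_discharge = integer(), gos_3to6m = integer(),
                 gos_1y = integer())
}
.empty_md <- function() {
  tibble::tibble(patient_id = character(),
                 vial_time = as.POSIXct(character(), tz = "UTC"),
                 marker = character(), value = numeric())
}
.empty_pressures <- function() {
  tibble::tibble(patient_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 variable = character(), value = numeric())
}

#' @export
print.md_cohort <- function(x, ...) {
  cat("<md_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$md), " marker values, ",
      nrow(x$pressures), " pressure samples\n", sep = "")
  invisible(x)
}

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a cohort to tidy long CSV files
#'
#' Writes `md.csv`, `pressures.csv` and `patients.csv` (UTF-8, ISO-8601
#' timestamps) into `path`. An empty cohort yields header-only files.
#'
#' @param cohort an `md_cohort`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "md_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  md <- dplyr::mutate(cohort$md, vial_time = .fmt_time(.data$vial_time))
  pr <- dplyr::mutate(cohort$pressures, timestamp = .fmt_time(.data$timestamp))
  readr::write_csv(md, file.path(path, "md.csv"), progress = FALSE)
  readr::write_csv(pr, file.path(path, "pressures.csv"), progress = FALSE)
  readr::write_csv(cohort$patients, file.path(path, "patients.csv"),
                   progress = FALSE)
  invisible(path)
}

.read_time <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")

#' Read a cohort from tidy long CSV files
#'
#' Inverse of [write_cohort()]. Malformed rows (non-positive marker values,
#' unknown markers or pressure variables, unparseable timestamps) are
#' reported with their file and line numbers.
#'
#' @param path directory containing `md.csv`, `pressures.csv`, `patients.csv`.
#' @return an `md_cohort`.
#' @export
read_cohort <- function(path) {
  md <- readr::read_csv(file.path(path, "md.csv"),
                        col_types = "cccd", progress = FALSE)
  pr <- readr::read_csv(file.path(path, "pressures.csv"),
                        col_types = "cccd", progress = FALSE)
  pat <- readr::read_csv(file.path(path, "patients.csv"),
                         col_types = "cciii", progress = FALSE)

  bad <- which(!(md$marker %in% MD_MARKERS) | is.na(md$value) | md$value <= 0)
  if (length(bad)) {
    b <- bad[1]
    stop(sprintf(
      "md.csv line %d: invalid value %s for marker '%s' (patient %s, time %s)",
      b + 1L, format(md$value[b]), md$marker[b], md$patient_id[b],
      md$vial_time[b]))
  }
  vt <- .read_time(md$vial_time)
  if (anyNA(vt) && nrow(md)) {
    b <- which(is.na(vt))[1]
    stop(sprintf("md.csv line %d: unparseable timestamp '%s'",
                 b + 1L, md$vial_time[b]))
  }
  badp <- which(!(pr$variable %in% c("ICP", "MAP")) | is.na(pr$value))
  if (length(badp)) {
    b <- badp[1]
    stop(sprintf("pressures.csv line %d: invalid row (patient %s, variable %s)",
                 b + 1L, pr$patient_id[b], pr$variable[b]))
  }
  ord <- order(md$patient_id, vt, match(md$marker, MD_MARKERS))
  md <- md[ord, ]
  md$vial_time <- vt[ord]
  pr$timestamp <- .read_time(pr$timestamp)
  pr <- dplyr::arrange(pr, .data$patient_id, .data$variable, .data$timestamp)
  out <- list(patients = pat, md = tibble::as_tibble(md),
              pressures = tibble::as_tibble(pr))
  class(out) <- "md_cohort"
  out
}

#' Simulate a longitudinal panel with ARMA(1,1) mixed-model structure
#'
#' Direct generator for mixed-model parameter-recovery studies:
#' `y_it = intercept + x_it * beta + b_i + s * arma11(phi, theta)` with
#' `b_i ~ N(0, sigma_b^2)` and unit-variance standard-normal predictors.
#'
#' @param n_patients,n_hours panel dimensions (balanced).
#' @param beta named vector of predictor coefficients (one column per name).
#' @param sigma_b between-patient intercept SD.
#' @param sigma stationary SD of the within-patient residual process.
#' @param phi,theta ARMA(1,1) residual correlation parameters.
#' @param intercept fixed intercept.
#' @param seed RNG seed.
#' @return tibble with patient_id, hour_index, the predictor columns and `y`.
#' @export
simulate_arma_panel <- function(n_patients, n_hours, beta = c(x = 0.5),
                                sigma_b = 2, sigma = 1, phi = 0.8,
                                theta = 0.2, intercept = 0, seed = 1L) {
  stopifnot(abs(phi) < 1, abs(theta) < 1, sigma_b >= 0, sigma > 0)
  set.seed(seed)
  innov_sd <- sigma / sqrt((1 + 2 * phi * theta + theta^2) / (1 - phi^2))
  rows <- lapply(seq_len(n_patients), function(i) {
    X <- matrix(rnorm(n_hours * length(beta)), n_hours,
                dimnames = list(NULL, names(beta)))
    y <- intercept + as.vector(X %*% beta) + rnorm(1, sd = sigma_b) +
      .sim_arma11(n_hours, phi, theta, innov_sd)
    tibble::tibble(patient_id = sprintf("P%03d", i),
                   hour_index = seq_len(n_hours) - 1L,
                   tibble::as_tibble(X), y = y)
  })
  dplyr::bind_rows(rows)
}
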