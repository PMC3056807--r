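# Preprocessing: from raw cohort tables to per-patient hourly aligned frames.
#
# Order of operations: transfer-time shift -> limiters -> (optional manual
# exclusions) -> pivot to vials -> hour-prior pressure alignment ->
# complete-set extraction -> ratios (from raw concentrations) -> normalizing
# transforms -> hour indexing.

#' Default out-of-range limits per marker
#'
#' The assay reports nonsensical extreme values occasionally (notably very
#' low pyruvate, which explodes the lactate:pyruvate ratio); values outside
#' these closed intervals are clamped to the nearer bound. The floors/caps
#' are configurable; the pyruvate floor of 10 uM/l is the load-bearing one.
#'
#' @return named list of `c(lower, upper)` per marker; glucose/lactate in
#'   mM/l, pyruvate/glycerol in uM/l.
#' @export
md_limits <- function() {
  list(glucose = c(0.05, 20), lactate = c(0.10, 25),
       pyruvate = c(10, 1500), glycerol = c(5, 5000))
}

#' Adjust vial times for the membrane-to-vial transfer delay
#'
#' Dialysate needs a fixed transfer time to travel from the catheter membrane
#' to the collection vial; the chemistry in a vial stamped at `vial_time`
#' reflects the membrane `delay_minutes` earlier.
#'
#' @param md long tibble with a `vial_time` column (POSIXct).
#' @param delay_minutes non-negative delay; default 17 minutes.
#' @return `md` with a `membrane_time` column; ordering is preserved.
#' @export
shift_transfer_time <- function(md, delay_minutes = 17) {
  stopifnot(delay_minutes >= 0)
  dplyr::mutate(md, membrane_time = .data$vial_time - 60 * delay_minutes)
}

#' Clamp out-of-range marker values
#'
#' @param md long tibble with `marker` and `value` columns.
#' @param limits named list of `c(lower, upper)` per marker, as from
#'   [md_limits()].
#' @return `md` with clamped values; a `clamp_log` attribute counts clamps
#'   per marker.
#' @export
apply_limiters <- function(md, limits = md_limits()) {
  clamped <- integer(0)
  for (mk in names(limits)) {
    sel <- md$marker == mk & !is.na(md$value)
    lo <- limits[[mk]][1]
    hi <- limits[[mk]][2]
    n_out <- sum(md$value[sel] < lo | md$value[sel] > hi)
    md$value[sel] <- pmin(pmax(md$value[sel], lo), hi)
    clamped[mk] <- n_out
  }
  attr(md, "clamp_log") <- tibble::tibble(marker = names(clamped),
                                          n_clamped = unname(clamped))
  md
}

#' Lactate:pyruvate and lactate:glucose ratios
#'
#' Units are harmonized so both ratios are dimensionless: lactate (mM/l) is
#' converted to uM/l against pyruvate (uM/l); glucose shares lactate's units.
#'
#' @param glucose,lactate,pyruvate raw concentrations (post-limiting, > 0).
#' @return list with `lp_ratio` and `lg_ratio`.
#' @export
compute_ratios <- function(glucose, lactate, pyruvate) {
  ok <- is.na(glucose) | is.na(lactate) | is.na(pyruvate) |
    (glucose > 0 & lactate > 0 & pyruvate > 0)
  if (!all(ok)) {
    stop("non-positive concentration in ratio computation at row(s) ",
         paste(head(which(!ok), 5), collapse = ", "))
  }
  list(lp_ratio = (lactate * 1000) / pyruvate, lg_ratio = lactate / glucose)
}

#' Normalizing transforms for a wide marker frame
#'
#' Adds `<marker>_t` columns: square root for glucose, lactate and pyruvate,
#' log10 for glycerol. Ratios are left untransformed unless
#' `transform_ratios` is set (then both ratios are log10 transformed).
#'
#' @param frame wide tibble with raw `glucose`, `lactate`, `pyruvate`,
#'   `glycerol` columns (and optionally `lp_ratio`, `lg_ratio`).
#' @param transform_ratios also log10-transform the ratios in place?
#' @return the frame with transformed columns appended.
#' @export
transform_markers <- function(frame, transform_ratios = FALSE) {
  for (mk in MD_MARKERS) {
    frame[[paste0(mk, "_t")]] <- md_transform(frame[[mk]], mk)
  }
  if (transform_ratios) {
    frame$lp_ratio <- log10(frame$lp_ratio)
    frame$lg_ratio <- log10(frame$lg_ratio)
  }
  frame
}

#' Hour-prior pressure means for each vial
#'
#' For each vial's membrane time `t`, averages ICP over the half-open window
#' `(t - window, t]` and CPP over timestamp-matched MAP/ICP pairs in the same
#' window (`cpp_mode = "separate"` subtracts the window means instead).
#' Rows whose window has less than `min_coverage` of the expected samples
#' (for ICP or for CPP pairs) get `NA` pressures and are logged.
#'
#' @param vials tibble with `patient_id` and `membrane_time`.
#' @param pressures long tibble (patient_id, timestamp, variable, value) with
#'   variable in `ICP`/`MAP`.
#' @param window_minutes averaging window length.
#' @param min_coverage minimum fraction of expected pressure samples.
#' @param cpp_mode `"matched"` (pairwise MAP-ICP) or `"separate"`.
#' @return `vials` with `icp_hour`, `cpp_hour` and coverage columns; a
#'   `coverage_log` attribute lists low-coverage rows.
#' @export
align_pressures <- function(vials, pressures, window_minutes = 60,
                            min_coverage = 0.5,
                            cpp_mode = c("matched", "separate")) {
  cpp_mode <- match.arg(cpp_mode)
  if (!nrow(vials)) {
    vials$icp_hour <- numeric(0)
    vials$cpp_hour <- numeric(0)
    return(vials)
  }
  if (!nrow(pressures)) {
    warning("pressure streams do not overlap the MD window; empty alignment")
    vials$icp_hour <- NA_real_
    vials$cpp_hour <- NA_real_
    return(vials[0, ])
  }
  P <- data.table::dcast(data.table::as.data.table(pressures),
                         patient_id + timestamp ~ variable,
                         value.var = "value", fun.aggregate = mean)
  if (is.null(P$ICP)) P$ICP <- NA_real_
  if (is.null(P$MAP)) P$MAP <- NA_real_
  # sampling interval per patient, for coverage accounting
  dt_pat <- P[, list(dt_min = {
    d <- as.numeric(diff(sort(unique(timestamp))), units = "mins")
    if (length(d)) median(d) else NA_real_
  }), by = "patient_id"]

  V <- data.table::as.data.table(vials[, c("patient_id", "membrane_time")])
  V$row_id <- seq_len(nrow(V))
  V$win_lo <- V$membrane_time - 60 * window_minutes
  V$win_hi <- V$membrane_time
  agg <- P[V, on = c("patient_id", "timestamp>win_lo", "timestamp<=win_hi"),
           list(row_id = i.row_id,
                icp_hour = mean(ICP, na.rm = TRUE),
                n_icp = sum(!is.na(ICP)),
                cpp_hour = if (cpp_mode == "matched") {
                  mean(MAP - ICP, na.rm = TRUE)
                } else {
                  mean(MAP, na.rm = TRUE) - mean(ICP, na.rm = TRUE)
                },
                n_cpp = sum(!is.na(MAP) & !is.na(ICP))),
           by = .EACHI]
  agg <- merge(agg[, c("patient_id", "row_id", "icp_hour", "n_icp",
                       "cpp_hour", "n_cpp")],
               dt_pat, by = "patient_id", all.x = TRUE)
  data.table::setorderv(agg, "row_id")
  expected <- window_minutes / agg$dt_min
  cov_icp <- agg$n_icp / expected
  cov_cpp <- agg$n_cpp / expected
  low <- is.na(cov_icp) | cov_icp < min_coverage | cov_cpp < min_coverage
  out <- vials
  out$icp_hour <- ifelse(low | !is.finite(agg$icp_hour), NA_real_, agg$icp_hour)
  out$cpp_hour <- ifelse(low | !is.finite(agg$cpp_hour), NA_real_, agg$cpp_hour)
  attr(out, "coverage_log") <- tibble::tibble(
    patient_id = vials$patient_id[low],
    membrane_time = vials$membrane_time[low],
    reason = "pressure coverage below threshold")
  out
}

#' Retain only complete marker sets with aligned pressures
#'
#' A row survives only if all four markers are present and both hour-prior
#' pressures are finite.
#'
#' @param frames wide tibble with the four marker columns and
#'   `icp_hour`/`cpp_hour`.
#' @return filtered tibble; a `drop_report` attribute gives per-patient
#'   retained/dropped counts.
#' @export
extract_complete_sets <- function(frames) {
  need <- c(MD_MARKERS, "icp_hour", "cpp_hour")
  ok <- stats::complete.cases(frames[, need])
  report <- frames |>
    dplyr::mutate(.ok = ok) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(retained = sum(.data$.ok), dropped = sum(!.data$.ok),
                     .groups = "drop")
  out <- frames[ok, setdiff(names(frames), ".ok")]
  attr(out, "drop_report") <- report
  out
}

#' Preprocessing configuration
#'
#' @param delay_minutes membrane-to-vial transfer time (min).
#' @param limits per-marker clamp intervals, as from [md_limits()].
#' @param window_minutes hour-prior pressure window length.
#' @param min_coverage minimum pressure coverage fraction in the window.
#' @param cpp_mode `"matched"` or `"separate"`; see [align_pressures()].
#' @param transform_ratios log10-transform the ratios too?
#' @param exclusions optional tibble (patient_id, start, end) of manually
#'   flagged artifact intervals; vials with membrane time inside an interval
#'   are removed.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(delay_minutes = 17, limits = md_limits(),
                              window_minutes = 60, min_coverage = 0.5,
                              cpp_mode = "matched", transform_ratios = FALSE,
                              exclusions = NULL) {
  structure(list(delay_minutes = delay_minutes, limits = limits,
                 window_minutes = window_minutes, min_coverage = min_coverage,
                 cpp_mode = cpp_mode, transform_ratios = transform_ratios,
                 exclusions = exclusions),
            class = "preprocess_config")
}

#' Preprocess a cohort into an aligned hourly frame
#'
#' Runs the full cleaning chain and returns one row per complete MD hour:
#' raw (limited) marker values, ratios computed from raw concentrations,
#' transformed markers, hour-prior mean ICP and CPP, and an integer
#' `hour_index` counting clock hours from each patient's first retained vial.
#'
#' @param cohort an `md_cohort` (simulated or read from CSV exports).
#' @param config a [preprocess_config()].
#' @return the aligned tibble; attributes `clamp_log`, `coverage_log` and
#'   `drop_report` carry the preprocessing audit trail.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  md <- shift_transfer_time(cohort$md, config$delay_minutes)
  md <- apply_limiters(md, config$limits)
  clamp_log <- attr(md, "clamp_log")
  if (!is.null(config$exclusions) && nrow(config$exclusions)) {
    for (k in seq_len(nrow(config$exclusions))) {
      ex <- config$exclusions[k, ]
      md <- md[!(md$patient_id == ex$patient_id &
                   md$membrane_time >= ex$start &
                   md$membrane_time <= ex$end), ]
    }
  }
  wide <- tidyr::pivot_wider(md, id_cols = c("patient_id", "membrane_time"),
                             names_from = "marker", values_from = "value")
  for (mk in MD_MARKERS) if (is.null(wide[[mk]])) wide[[mk]] <- NA_real_
  wide <- dplyr::arrange(wide, .data$patient_id, .data$membrane_time)
  wide <- align_pressures(wide, cohort$pressures,
                          window_minutes = config$window_minutes,
                          min_coverage = config$min_coverage,
                          cpp_mode = config$cpp_mode)
  coverage_log <- attr(wide, "coverage_log")
  wide <- extract_complete_sets(wide)
  drop_report <- attr(wide, "drop_report")

  rat <- compute_ratios(wide$glucose, wide$lactate, wide$pyruvate)
  wide$lp_ratio <- rat$lp_ratio
  wide$lg_ratio <- rat$lg_ratio
  wide <- transform_markers(wide, transform_ratios = config$transform_ratios)
  wide <- wide |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(hour_index = as.integer(round(as.numeric(
      difftime(.data$membrane_time, min(.data$membrane_time),
               units = "hours"))))) |>
    dplyr::ungroup()
  if (!is.null(cohort$patients) && nrow(cohort$patients)) {
    wide <- dplyr::left_join(
      wide, cohort$patients[, c("patient_id", "location")], by = "patient_id")
  } else {
    wide$location <- NA_character_
  }
  cols <- c("patient_id", "location", "hour_index", "membrane_time",
            MD_MARKERS, MD_RATIOS, paste0(MD_MARKERS, "_t"),
            "icp_hour", "cpp_hour")
  out <- wide[, cols]
  attr(out, "clamp_log") <- clamp_log
  attr(out, "coverage_log") <- coverage_log
  attr(out, "drop_report") <- drop_report
  out
}
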