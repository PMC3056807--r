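# Outcome comparisons: per-patient summaries of MD and pressures against the
# best Glasgow Outcome Scale score, by one-way ANOVA and Kruskal-Wallis.

#' Per-patient outcome table
#'
#' Summarizes each patient's monitoring period (mean pressures, mean markers
#' and ratios in raw units, hours and percentage of monitoring with the
#' lactate:pyruvate ratio above a threshold) alongside the best GOS score
#' (the maximum over the available follow-up epochs). Patients with fewer
#' than `min_hours` complete MD hours, or with no GOS score at all, are
#' flagged excluded with a reason.
#'
#' @param data aligned tibble.
#' @param gos tibble with `patient_id`, `gos_discharge`, `gos_3to6m`,
#'   `gos_1y` (NAs allowed).
#' @param lp_threshold lactate:pyruvate ratio counted as "increased" above
#'   this value (default 25, a conventional clinical cutoff).
#' @param min_hours minimum complete MD hours for inclusion (default 12).
#' @return tibble, one row per patient, with `included` and
#'   `exclusion_reason` columns.
#' @export
build_outcome_table <- function(data, gos, lp_threshold = 25,
                                min_hours = 12) {
  summ <- data |>
    dplyr::group_by(.data$patient_id, .data$location) |>
    dplyr::summarise(
      monitored_hours = dplyr::n(),
      lp_hours_above = sum(.data$lp_ratio > lp_threshold),
      mean_icp = mean(.data$icp_hour), mean_cpp = mean(.data$cpp_hour),
      dplyr::across(dplyr::all_of(c(MD_MARKERS, MD_RATIOS)), mean),
      .groups = "drop") |>
    dplyr::mutate(lp_pct_above = 100 * .data$lp_hours_above /
                    .data$monitored_hours)
  gos_cols <- intersect(c("gos_discharge", "gos_3to6m", "gos_1y"),
                        names(gos))
  gm <- as.matrix(gos[, gos_cols])
  best <- suppressWarnings(apply(gm, 1, max, na.rm = TRUE))
  best[!is.finite(best)] <- NA_real_
  gos_best <- tibble::tibble(patient_id = gos$patient_id,
                             best_gos = as.integer(best))
  out <- dplyr::left_join(summ, gos_best, by = "patient_id")
  out$exclusion_reason <- NA_character_
  out$exclusion_reason[out$monitored_hours < min_hours] <-
    sprintf("fewer than %d hours of MD", min_hours)
  out$exclusion_reason[is.na(out$best_gos)] <- "no GOS score recorded"
  out$included <- is.na(out$exclusion_reason)
  attr(out, "lp_threshold") <- lp_threshold
  attr(out, "min_hours") <- min_hours
  out
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test of equal group means.
#'
#' @param values numeric vector.
#' @param groups grouping vector (coerced to factor; empty levels dropped).
#' @return list with `statistic` (F), `p_value`, `df` (between, within).
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("anova_oneway needs at least 2 non-empty groups")
  if (length(values) <= nlevels(g)) stop("total n must exceed group count")
  # classical equal-variance F via the linear-model decomposition; unlike
  # oneway.test this tolerates singleton groups (they add between-group SS
  # but no within-group degrees of freedom)
  tab <- stats::anova(lm(values ~ g))
  f <- tab$`F value`[1]
  if (!is.finite(f)) f <- 0
  p <- tab$`Pr(>F)`[1]
  if (!is.finite(p)) p <- 1
  list(statistic = f, p_value = p, df = tab$Df)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference.
#'
#' @inheritParams anova_oneway
#' @return list with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("kruskal_wallis needs at least 2 non-empty groups")
  if (stats::var(values) == 0) {
    return(list(statistic = 0, p_value = 1, df = nlevels(g) - 1))
  }
  kt <- kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Screen every outcome-table summary against GOS groups
#'
#' Runs both the one-way ANOVA and the Kruskal-Wallis test of each
#' per-patient summary column across best-GOS groups (included patients
#' only), and reports whether findings significant at `alpha` agree between
#' the two tests.
#'
#' @param table an outcome table from [build_outcome_table()].
#' @param columns summary columns to test.
#' @param alpha significance level for the concordance check.
#' @return tibble with per-column F/H statistics, p-values and a
#'   `concordant` flag; attribute `n_groups` records the GOS groups used.
#' @export
outcome_screen <- function(table,
                           columns = c("mean_icp", "mean_cpp", MD_MARKERS,
                                       MD_RATIOS, "lp_hours_above",
                                       "lp_pct_above"),
                           alpha = 0.05) {
  t2 <- table[table$included, ]
  groups <- droplevels(factor(t2$best_gos))
  if (nlevels(groups) < 2) {
    warning("only one GOS group present; tests skipped")
    return(tibble::tibble())
  }
  rows <- lapply(columns, function(cl) {
    av <- anova_oneway(t2[[cl]], groups)
    kw <- kruskal_wallis(t2[[cl]], groups)
    tibble::tibble(
      variable = cl, f_statistic = av$statistic, p_anova = av$p_value,
      h_statistic = kw$statistic, p_kruskal = kw$p_value,
      concordant = (av$p_value < alpha) == (kw$p_value < alpha))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_groups") <- nlevels(groups)
  attr(out, "n_patients") <- nrow(t2)
  out
}
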