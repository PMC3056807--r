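mk_md <- function(times, marker = "lactate", value = 5,
                  patient = "P01") {
  tibble::tibble(patient_id = patient,
                 vial_time = as.POSIXct(times, tz = "UTC"),
                 marker = marker, value = value)
}

test_that("transfer-time shift subtracts the delay and preserves spacing", {
  md <- mk_md(c("2020-01-01 12:00:00", "2020-01-01 13:00:00"))
  out <- shift_transfer_time(md, 17)
  expect_equal(format(out$membrane_time[1], "%H:%M"), "11:43")
  expect_equal(as.numeric(diff(out$membrane_time), units = "mins"), 60)
  expect_equal(shift_transfer_time(md, 0)$membrane_time, md$vial_time)
})

test_that("limiters clamp to the nearer bound, log counts and are idempotent", {
  md <- tibble::tibble(patient_id = "P01",
                       vial_time = as.POSIXct("2020-01-01", tz = "UTC"),
                       marker = c("glycerol", "pyruvate", "lactate"),
                       value = c(9000, 4, 5))
  lim <- md_limits()
  out <- apply_limiters(md, lim)
  expect_equal(out$value, c(lim$glycerol[2], lim$pyruvate[1], 5))
  log <- attr(out, "clamp_log")
  expect_equal(sum(log$n_clamped), 2L)
  again <- apply_limiters(out, lim)
  expect_equal(again$value, out$value)
  expect_equal(sum(attr(again, "clamp_log")$n_clamped), 0L)
})

test_that("ratio arithmetic harmonizes units and bounds the LP ratio after limiting", {
  r <- compute_ratios(glucose = 2.0, lactate = 5.0, pyruvate = 200)
  expect_equal(r$lp_ratio, 25)
  expect_equal(r$lg_ratio, 2.5)
  r2 <- compute_ratios(1.0, 3.0, 100)
  expect_equal(r2$lp_ratio, 30)
  expect_equal(r2$lg_ratio, 3)
  # pyruvate below its floor is clamped first, keeping the ratio finite
  r3 <- compute_ratios(1.0, 5.0, md_limits()$pyruvate[1])
  expect_equal(r3$lp_ratio, 5000 / md_limits()$pyruvate[1])
  expect_error(compute_ratios(0, 5, 100), "non-positive")
})

test_that("normalizing transforms match their definitions", {
  fr <- tibble::tibble(glucose = 4, lactate = 9, pyruvate = 16,
                       glycerol = 100, lp_ratio = 30, lg_ratio = 2)
  tr <- transform_markers(fr)
  expect_equal(tr$glucose_t, 2)
  expect_equal(tr$lactate_t, 3)
  expect_equal(tr$pyruvate_t, 4)
  expect_equal(tr$glycerol_t, 2)
  expect_equal(tr$lp_ratio, 30)  # ratios untouched by default
  tr2 <- transform_markers(fr, transform_ratios = TRUE)
  expect_equal(tr2$lg_ratio, log10(2))
})

press_stream <- function(minutes, icp, map, patient = "P01") {
  base <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  tibble::tibble(
    patient_id = patient,
    timestamp = rep(base + 60 * minutes, 2),
    variable = rep(c("ICP", "MAP"), each = length(minutes)),
    value = c(icp, map))
}

test_that("hour-prior alignment averages the half-open window", {
  base <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  vials <- tibble::tibble(patient_id = "P01", membrane_time = base + 3600)
  pr <- press_stream(1:60, icp = rep(12, 60), map = rep(82, 60))
  out <- align_pressures(vials, pr)
  expect_equal(out$icp_hour, 12)
  expect_equal(out$cpp_hour, 70)

  pr2 <- press_stream(1:60, icp = rep(c(10, 20), 30), map = rep(80, 60))
  out2 <- align_pressures(vials, pr2)
  expect_equal(out2$icp_hour, 15)
})

test_that("50% pressure coverage is the retention boundary", {
  base <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  vials <- tibble::tibble(patient_id = "P01", membrane_time = base + 3600)
  # need >1 vial worth of stream for a sampling-interval estimate
  keep30 <- press_stream(31:60, icp = rep(12, 30), map = rep(80, 30))
  out <- align_pressures(vials, keep30)
  expect_false(is.na(out$icp_hour))
  keep29 <- press_stream(32:60, icp = rep(12, 29), map = rep(80, 29))
  out2 <- align_pressures(vials, keep29)
  expect_true(is.na(out2$icp_hour))
  expect_equal(nrow(attr(out2, "coverage_log")), 1L)
})

test_that("complete-set extraction drops and reports incomplete rows", {
  fr <- tibble::tibble(
    patient_id = "P01",
    glucose = c(rep(2, 7), NA, 2, 2),
    lactate = c(rep(5, 8), NA, 5),
    pyruvate = rep(150, 10),
    glycerol = c(rep(80, 9), NA),
    icp_hour = rep(12, 10), cpp_hour = rep(70, 10))
  out <- extract_complete_sets(fr)
  expect_equal(nrow(out), 7L)
  rep <- attr(out, "drop_report")
  expect_equal(rep$dropped, 3L)
  expect_equal(rep$retained, 7L)
  # idempotent
  out2 <- extract_complete_sets(out)
  expect_equal(nrow(out2), 7L)
})

test_that("full preprocessing retains every complete vial when nothing is missing", {
  cfg <- tiny_config(n_patients = 5, hours_mean = 20, missing_rate = 0,
                     seed = 8)
  ch <- simulate_cohort(cfg)
  al <- preprocess_cohort(ch)
  n_vials <- nrow(ch$md) / 4
  expect_equal(nrow(al), n_vials)
  expect_true(all(diff(al$hour_index[al$patient_id == al$patient_id[1]]) > 0))
  expect_true(all(is.finite(al$icp_hour)))
})

test_that("manual exclusion intervals remove the flagged vials", {
  cfg <- tiny_config(n_patients = 2, hours_mean = 10, missing_rate = 0,
                     seed = 8)
  ch <- simulate_cohort(cfg)
  al0 <- preprocess_cohort(ch)
  win <- range(al0$membrane_time[al0$patient_id == "P001"])
  ex <- tibble::tibble(patient_id = "P001", start = win[1],
                       end = win[1] + 2 * 3600)
  al1 <- preprocess_cohort(ch, preprocess_config(exclusions = ex))
  expect_lt(sum(al1$patient_id == "P001"), sum(al0$patient_id == "P001"))
  expect_equal(sum(al1$patient_id == "P002"), sum(al0$patient_id == "P002"))
})
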