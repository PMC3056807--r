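outcome_fixture <- function() {
  mk_pat <- function(id, n, lp = 20, icp = 12, cpp = 70) {
    tibble::tibble(patient_id = id, location = "pericontusional",
                   hour_index = seq_len(n) - 1L,
                   glucose = 2, lactate = 5, pyruvate = 160, glycerol = 200,
                   lp_ratio = rep(lp, length.out = n), lg_ratio = 2.5,
                   glucose_t = sqrt(2), lactate_t = sqrt(5),
                   pyruvate_t = sqrt(160), glycerol_t = log10(200),
                   icp_hour = icp, cpp_hour = cpp)
  }
  dplyr::bind_rows(
    mk_pat("A", 20, lp = c(20, 30, 50, 20)),
    mk_pat("B", 11),
    mk_pat("C", 30, icp = 25))
}

test_that("the outcome table applies the best-GOS rule and inclusion criteria", {
  d <- outcome_fixture()
  gos <- tibble::tibble(patient_id = c("A", "B", "C"),
                        gos_discharge = c(3L, 4L, NA),
                        gos_3to6m = c(4L, 5L, NA),
                        gos_1y = c(4L, NA, NA))
  ot <- build_outcome_table(d, gos, lp_threshold = 40, min_hours = 12)
  expect_equal(ot$best_gos[ot$patient_id == "A"], 4L)
  expect_false(ot$included[ot$patient_id == "B"])
  expect_match(ot$exclusion_reason[ot$patient_id == "B"], "fewer than 12")
  expect_false(ot$included[ot$patient_id == "C"])
  expect_match(ot$exclusion_reason[ot$patient_id == "C"], "no GOS")
  # LP burden: series (20,30,50,20) recycled over 20 h, threshold 40
  expect_equal(ot$lp_hours_above[ot$patient_id == "A"], 5L)
  expect_equal(ot$lp_pct_above[ot$patient_id == "A"], 25)
})

test_that("exclusion rules are order-independent", {
  d <- outcome_fixture()
  gos <- tibble::tibble(patient_id = c("A", "B", "C"),
                        gos_discharge = c(3L, 4L, 5L),
                        gos_3to6m = NA_integer_, gos_1y = NA_integer_)
  set.seed(1)
  ot1 <- build_outcome_table(d, gos)
  shuf <- d[sample.int(nrow(d)), ]
  ot2 <- build_outcome_table(shuf, gos[c(3, 1, 2), ])
  expect_equal(ot1[order(ot1$patient_id), ],
               ot2[order(ot2$patient_id), ])
})

test_that("one-way ANOVA matches brute-force sums of squares and the t-test identity", {
  vals <- c(3.1, 4.0, 5.2, 6.3, 5.9, 7.1, 8.0, 7.5, 9.2)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  av <- anova_oneway(vals, grp)
  expect_equal(av$statistic, brute_anova_F(vals, grp), tolerance = 1e-10)

  # identical groups: F = 0, p = 1
  av0 <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(av0$statistic, 0)
  expect_equal(av0$p_value, 1)

  # complete separation
  avs <- anova_oneway(c(0, 0, 0, 10, 10, 10) + rnorm(6, sd = 1e-3),
                      rep(c("a", "b"), each = 3))
  expect_lt(avs$p_value, 1e-6)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(2)
  v <- rnorm(14)
  g <- rep(c("a", "b"), 7)
  av2 <- anova_oneway(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(av2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_error(anova_oneway(1:5, rep("a", 5)), "2 non-empty groups")
})

test_that("Kruskal-Wallis matches brute-force rank arithmetic with and without ties", {
  # fully separated ranks, 4 + 4
  v1 <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g1 <- rep(c("a", "b"), each = 4)
  kw1 <- kruskal_wallis(v1, g1)
  expect_equal(kw1$statistic, brute_kw_H(v1, g1), tolerance = 1e-10)

  # tied values on a 6-value fixture
  v2 <- c(1, 2, 2, 3, 3, 3)
  g2 <- c("a", "a", "b", "b", "c", "c")
  kw2 <- kruskal_wallis(v2, g2)
  expect_equal(kw2$statistic, brute_kw_H(v2, g2), tolerance = 1e-10)

  # all tied: H = 0, p = 1
  kw0 <- kruskal_wallis(rep(5, 6), g2)
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # invariance under monotone transformation
  set.seed(3)
  v3 <- rnorm(15)
  g3 <- rep(c("a", "b", "c"), 5)
  expect_equal(kruskal_wallis(v3, g3)$statistic,
               kruskal_wallis(exp(v3), g3)$statistic, tolerance = 1e-12)
})

test_that("outcome screening reports concordant test pairs and degenerate groupings", {
  set.seed(4)
  n <- 40
  ot <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    location = "pericontusional",
    glucose = rnorm(n, 2), lactate = rnorm(n, 5), pyruvate = rnorm(n, 160),
    glycerol = rnorm(n, 200), lp_ratio = rnorm(n, 30), lg_ratio = rnorm(n, 3),
    mean_icp = rnorm(n, 14, 3), mean_cpp = rnorm(n, 66, 5),
    monitored_hours = 50, lp_hours_above = rpois(n, 5),
    lp_pct_above = runif(n, 0, 30),
    best_gos = sample(c(1, 3, 4, 5), n, replace = TRUE),
    included = TRUE, exclusion_reason = NA_character_)
  ot$mean_icp <- ot$mean_icp - 1.5 * ot$best_gos
  sc <- outcome_screen(ot)
  expect_true(all(c("p_anova", "p_kruskal", "concordant") %in% names(sc)))
  expect_lt(sc$p_anova[sc$variable == "mean_icp"], 0.05)

  ot$best_gos <- 4
  expect_warning(sc0 <- outcome_screen(ot), "one GOS group")
  expect_equal(nrow(sc0), 0L)
})
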