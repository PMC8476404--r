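# Visit assessment: composition of ages, z-scores, interval growth,
# classification and plausibility.

term_child <- function() {
  list(child_id = "C1", birth_date = as.Date("2018-08-01"),
       gestational_age_weeks = 40, referred_as_preterm = FALSE,
       sex = "male")
}

test_that("a complete term visit yields all three z-scores and colours", {
  refs <- test_refs()
  age <- 120
  visit <- list(visit_date = as.Date("2018-08-01") + age,
                weight_g = round(median_at("weight_for_age", "male", age) * 1000),
                length_cm = round(median_at("length_for_age", "male", age), 1))
  a <- assess_visit(term_child(), visit, NULL, refs)
  expect_equal(a$corrected_age_days, age)
  expect_true(all(!is.na(c(a$z_lhfa, a$z_wflh, a$z_wfa))))
  expect_true(all(abs(c(a$z_lhfa, a$z_wflh, a$z_wfa)) < 1))
  expect_equal(a$class_lhfa, "normal")
  expect_equal(a$colour_lhfa, "green")
  expect_false(a$implausible)
  # first-ever visit: no interval growth
  expect_equal(a$class_interval, "not_applicable")
  expect_true(is.na(a$interval_growth_g_per_day))
})

test_that("interval growth links to the previous weighed visit", {
  refs <- test_refs()
  b <- as.Date("2018-08-01")
  w1 <- round(median_at("weight_for_age", "male", 60) * 1000)
  visit <- list(visit_date = b + 90,
                weight_g = w1 + 23 * 30, length_cm = 59)
  prev <- list(visit_date = b + 60, weight_g = w1)
  a <- assess_visit(term_child(), visit, prev, refs)
  expect_equal(a$interval_growth_g_per_day, 23)
  expect_equal(a$class_interval, "adequate")  # 23 >= 20 g/day under 3 months
})

test_that("negative corrected age turns every classification not-applicable", {
  refs <- test_refs()
  child <- term_child()
  child$gestational_age_weeks <- 28  # 84 days early
  visit <- list(visit_date = child$birth_date + 30,
                weight_g = 2500, length_cm = 46)
  a <- assess_visit(child, visit, NULL, refs)
  expect_equal(a$corrected_age_days, -54)
  expect_equal(a$class_lhfa, "not_applicable")
  expect_equal(a$class_wflh, "not_applicable")
  expect_equal(a$class_wfa, "not_applicable")
  expect_equal(a$class_interval, "not_applicable")
})

test_that("a fabricated weight at raw z = 6 trips the implausibility flag", {
  refs <- test_refs()
  age <- 120
  tab <- refs$weight_for_age$male
  p <- interpolate_lms(tab, age)
  y6 <- lms_inverse_zscore(6, p$L, p$M, p$S)
  visit <- list(visit_date = as.Date("2018-08-01") + age,
                weight_g = y6 * 1000,
                length_cm = round(median_at("length_for_age", "male", age), 1))
  a <- assess_visit(term_child(), visit, NULL, refs)
  expect_true(a$implausible)
  expect_gt(a$z_wfa_raw, 5)
  # the adjusted (restricted) value is what classification sees
  expect_equal(a$class_wfa, "normal")
})

test_that("missing measurements leave the affected z undefined", {
  refs <- test_refs()
  visit <- list(visit_date = as.Date("2018-08-01") + 100,
                weight_g = 5000, length_cm = NA_real_)
  a <- assess_visit(term_child(), visit, NULL, refs)
  expect_true(is.na(a$z_lhfa))
  expect_true(is.na(a$z_wflh))
  expect_false(is.na(a$z_wfa))
})

test_that("unknown sex or missing birth date is a validation error", {
  refs <- test_refs()
  child <- term_child(); child$sex <- NA_character_
  visit <- list(visit_date = as.Date("2018-09-01"), weight_g = 4000,
                length_cm = 55)
  expect_error(assess_visit(child, visit, NULL, refs),
               class = "pdc_validation_error")
  child2 <- term_child(); child2$birth_date <- as.Date(NA)
  expect_error(assess_visit(child2, visit, NULL, refs),
               class = "pdc_validation_error")
})

test_that("cohort assessment is order-independent and skips broken records", {
  refs <- test_refs()
  children <- mk_children(3)
  children$sex[3] <- NA  # this child's visits must be skipped, with a log
  b <- children$birth_date[1]
  w30 <- round(median_at("weight_for_age", "male", 30) * 1000)
  visits <- rbind(
    mk_visits("K0001", b + c(30, 60, 90), weight_g = c(w30, w30 + 700, NA),
              length_cm = 53),
    mk_visits("K0002", b + 30, weight_g = w30, length_cm = 53),
    mk_visits("K0003", b + 30, weight_g = w30, length_cm = 53),
    mk_visits("GHOST", b + 30, weight_g = w30, length_cm = 53))
  a1 <- assess_cohort(children, visits, refs)
  expect_equal(nrow(a1), 4L)  # K0003 and GHOST dropped
  expect_gt(length(attr(a1, "issues")), 0L)
  # visit 3 of K0001 has no weight: its interval class is NA-condition,
  # and the previous *weighed* visit is visit 2 for any later linkage
  k1 <- a1[a1$child_id == "K0001", ]
  expect_equal(k1$is_first_visit, c(TRUE, FALSE, FALSE))
  expect_equal(k1$interval_growth_g_per_day[2], 700 / 30)
  expect_equal(k1$class_interval[3], "not_applicable")
  # permuting input rows changes nothing after the internal sort
  set.seed(1)
  a2 <- assess_cohort(children, visits[sample(nrow(visits)), ], refs)
  attr(a1, "issues") <- attr(a2, "issues") <- NULL
  expect_equal(a1, a2)
  # idempotence: assessing the assessment's visit columns again matches
  a3 <- assess_cohort(children, visits, refs)
  attr(a3, "issues") <- NULL
  expect_equal(a1, a3)
})

test_that("assessment classifications match the rule-table oracle on random visits", {
  refs <- test_refs()
  set.seed(99)
  n <- 1000
  ga <- ifelse(runif(n) < 0.5, runif(n, 27, 36.9), runif(n, 37, 42))
  b <- as.Date("2018-08-01")
  age <- sample(5:600, n, replace = TRUE)
  z_l <- rnorm(n, -1.5, 1.5)
  z_w <- rnorm(n, -1.5, 1.5)
  for (i in seq_len(n)) {
    child <- list(child_id = "X", birth_date = b,
                  gestational_age_weeks = ga[i], referred_as_preterm = FALSE,
                  sex = sample(c("male", "female"), 1))
    corr <- corrected_age(b, b + age[i], ga[i])$corrected_age_days
    gen_age <- max(corr, 0)
    len <- median_at("length_for_age", child$sex, gen_age, z = z_l[i])
    wt <- median_at("weight_for_age", child$sex, gen_age, z = z_w[i]) * 1000
    a <- assess_visit(child, list(visit_date = b + age[i], weight_g = wt,
                                  length_cm = len), NULL, refs)
    expect_identical(a$class_lhfa,
                     oracle_classify_z("length_for_age", a$z_lhfa, corr,
                                       wt / 1000, len))
    expect_identical(a$class_wflh,
                     oracle_classify_z("weight_for_length", a$z_wflh, corr,
                                       wt / 1000, len))
    expect_identical(a$class_wfa,
                     oracle_classify_z("weight_for_age", a$z_wfa, corr,
                                       wt / 1000, len))
  }
})
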