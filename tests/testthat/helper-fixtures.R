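# Shared fixtures: a cached reference set, small cohort builders, and
# independent oracles coded straight from the protocol's rule table
# (kept free of the package's classification code on purpose).

test_refs <- local({
  refs <- NULL
  function() {
    if (is.null(refs)) refs <<- synthetic_reference()
    refs
  }
})

# --- independent rule-table oracles -----------------------------------

MO <- 365.25 / 12

oracle_classify_z <- function(indicator, z, age_days, weight_kg, length_cm) {
  na <- switch(indicator,
    length_for_age = isTRUE(age_days < 0) || isTRUE(length_cm < 42),
    weight_for_length = isTRUE(length_cm < 45) || isTRUE(age_days < 0) ||
      isTRUE(weight_kg < 1.6),
    weight_for_age = isTRUE(age_days < 0) || isTRUE(weight_kg < 1.4))
  if (na) return("not_applicable")
  if (is.na(z)) return(NA_character_)
  if (z >= -2) "normal" else if (z >= -3) "moderate" else "severe"
}

oracle_classify_interval <- function(rate, age_days, prev_present) {
  if (is.na(age_days) || age_days < 0 || age_days >= 24 * MO || !prev_present) {
    return("not_applicable")
  }
  mo <- age_days / MO
  thr <- if (mo < 3) 20 else if (mo < 6) 15 else if (mo < 8) 10 else
         if (mo < 12) 6 else if (mo < 16) 5 else 4
  if (is.na(rate)) NA_character_ else if (rate >= thr) "adequate" else "inadequate"
}

# Measurement at z-score k, computed in the test from the closed form.
oracle_sd <- function(k, L, M, S) {
  if (L == 0) M * exp(S * k) else M * (1 + L * S * k)^(1 / L)
}

# --- cohort builders --------------------------------------------------

# One child per row, vectorised; defaults give a term, in-window child.
mk_children <- function(n, arm = "control", period = "pre",
                        ga = 40, referred = FALSE, sex = "male",
                        facility_id = paste0(substr(arm, 1, 1), "-F1"),
                        facility_type = "hospital",
                        birth_date = NULL, id_prefix = "K") {
  win <- default_periods()[[period]]
  if (is.null(birth_date)) birth_date <- win[1]
  data.frame(
    child_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    birth_date = rep(as.Date(birth_date), length.out = n),
    gestational_age_weeks = rep(ga, length.out = n),
    referred_as_preterm = rep(referred, length.out = n),
    birthweight_g = 2600,
    enrollment_date = rep(as.Date(birth_date), length.out = n) + 5,
    sex = rep(sex, length.out = n),
    facility_id = facility_id, facility_type = facility_type,
    arm = arm, enrollment_period = period,
    stringsAsFactors = FALSE)
}

mk_visits <- function(child_id, visit_date, weight_g = NA_real_,
                      length_cm = NA_real_, visit_type = "standard_growth",
                      corrected_age_recorded = FALSE,
                      lhfa = NA_character_, wflh = NA_character_,
                      wfa = NA_character_,
                      interval_cat = NA_character_,
                      interval_val = NA_real_, period = "pre") {
  n <- max(length(child_id), length(visit_date))
  data.frame(
    child_id = rep(child_id, length.out = n),
    visit_date = rep(as.Date(visit_date), length.out = n),
    visit_type = rep(visit_type, length.out = n),
    weight_g = rep(weight_g, length.out = n),
    length_cm = rep(length_cm, length.out = n),
    nurse_corrected_age_recorded = rep(corrected_age_recorded, length.out = n),
    nurse_lhfa = rep(lhfa, length.out = n),
    nurse_wflh = rep(wflh, length.out = n),
    nurse_wfa = rep(wfa, length.out = n),
    nurse_interval_growth_category = rep(interval_cat, length.out = n),
    nurse_interval_growth_value = rep(interval_val, length.out = n),
    period = rep(period, length.out = n),
    stringsAsFactors = FALSE)
}

# Median measurement for a sex/indicator at an index value, via the
# reference tables (used to construct visits with known gold classes).
median_at <- function(indicator, sex, index_value, z = 0) {
  tab <- test_refs()[[indicator]][[sex]]
  p <- interpolate_lms(tab, index_value)
  lms_inverse_zscore(z, p$L, p$M, p$S)
}

# --- worked-example fixture builders ----------------------------------

# One exposure group of single-visit children with prescribed recording
# counts, for completeness audits. Excluded rows (urgent-care visits
# after the cutover) are placed last and belong to term children.
mk_completeness_group <- function(arm, n_total, n_preterm, n_corr_age,
                                  n_lhfa_yes, n_lhfa_excluded,
                                  n_wfa_yes, n_wflh_yes, n_interval_yes = 0,
                                  id_prefix, cutover) {
  children <- mk_children(n_total, arm = arm, period = "post",
                          id_prefix = id_prefix,
                          ga = c(rep(32, n_preterm), rep(40, n_total - n_preterm)),
                          birth_date = default_periods()$post[1])
  n_inc <- n_total - n_lhfa_excluded
  first_n <- function(k) rep(c(TRUE, FALSE), c(k, n_total - k))
  visits <- mk_visits(
    children$child_id,
    visit_date = c(rep(children$birth_date[1] + 40, n_inc),
                   rep(cutover + 1, n_lhfa_excluded)),
    visit_type = rep(c("standard_growth", "other"), c(n_inc, n_lhfa_excluded)),
    corrected_age_recorded = first_n(n_corr_age),
    lhfa = ifelse(first_n(n_lhfa_yes), "normal", NA),
    wfa = ifelse(first_n(n_wfa_yes), "normal", NA),
    wflh = ifelse(first_n(n_wflh_yes), "normal", NA),
    interval_cat = ifelse(first_n(n_interval_yes), "adequate", NA),
    period = "post")
  list(children = children, visits = visits)
}

# Cohort with known gold classes for concordance audits: term children,
# in-range median measurements (gold "normal"/"adequate"), nurse entries
# split into agreeing and disagreeing ones.
concordance_fixture <- function(n_match, n_mismatch, metric = "lhfa",
                                arm = "intervention", period = "pre",
                                id_prefix = "C") {
  n <- n_match + n_mismatch
  children <- mk_children(n, arm = arm, period = period, id_prefix = id_prefix)
  b <- children$birth_date[1]
  len60 <- round(median_at("length_for_age", "male", 60), 1)
  wt60 <- round(median_at("weight_for_age", "male", 60) * 1000)
  if (metric == "lhfa") {
    visits <- mk_visits(children$child_id, b + 60, weight_g = wt60,
                        length_cm = len60,
                        lhfa = c(rep("normal", n_match),
                                 rep("severe", n_mismatch)),
                        period = period)
  } else {
    wt30 <- round(median_at("weight_for_age", "male", 30) * 1000)
    v1 <- mk_visits(children$child_id, b + 30, weight_g = wt30,
                    length_cm = 52, period = period)
    v2 <- mk_visits(children$child_id, b + 60, weight_g = wt30 + 25 * 30,
                    length_cm = len60,
                    interval_cat = c(rep("adequate", n_match),
                                     rep("inadequate", n_mismatch)),
                    period = period)
    visits <- rbind(v1, v2)
  }
  visits$group <- paste(arm, period, sep = "_")
  assess_cohort(children, visits, test_refs())
}

# Cohort engineered so each child's outcome flags at the target age are
# known by construction; flags is a logical matrix with columns
# stunted / underweight / wasted / inadequate. Wasting is only requested
# together with underweight (a light child for its length is lighter
# still for its age under these references).
outcome_fixture <- function(flags, arm = "intervention", period = "post",
                            target_mo = 6, id_prefix = "O") {
  n <- nrow(flags)
  children <- mk_children(n, arm = arm, period = period, id_prefix = id_prefix,
                          birth_date = default_periods()[[period]][1])
  b <- children$birth_date[1]
  t_days <- round(target_mo * DAYS_PER_MONTH)
  z_len <- ifelse(flags[, "stunted"], -2.6, -1)
  len <- vapply(z_len, function(z)
    median_at("length_for_age", "male", t_days, z = z), numeric(1))
  wt <- numeric(n)
  for (i in seq_len(n)) {
    w_wfa <- function(z) median_at("weight_for_age", "male", t_days, z = z) * 1000
    w_wfl <- function(z) median_at("weight_for_length", "male", len[i], z = z) * 1000
    wt[i] <-
      if (flags[i, "underweight"] && flags[i, "wasted"]) {
        min(w_wfa(-2.6), w_wfl(-2.6))
      } else if (flags[i, "underweight"]) {
        # between the weight-for-length and weight-for-age -2 cuts:
        # light for age but not for length
        (w_wfl(-2) + w_wfa(-2)) / 2
      } else if (flags[i, "wasted"]) {
        min(w_wfa(-1), w_wfl(-2.6))
      } else {
        max(w_wfa(-1), w_wfl(-1))
      }
  }
  gain <- ifelse(flags[, "inadequate"], 5, 20)  # threshold 10 g/day at 6 mo
  prev_wt <- wt - gain * 30
  visits <- rbind(
    mk_visits(children$child_id, b + t_days - 30, weight_g = prev_wt,
              period = period),
    mk_visits(children$child_id, b + t_days, weight_g = wt, length_cm = len,
              period = period))
  visits$group <- paste(arm, period, sep = "_")
  assessed <- assess_cohort(children, visits, test_refs())
  list(children = children, assessed = assessed)
}
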