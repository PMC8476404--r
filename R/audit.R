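# Visit-level data-quality audit: cohort filters, completeness of nurse
# recording, and concordance of nurse classifications against the
# gold-standard assessment, all tallied per exposure group.

EXPOSURE_GROUPS <- c("control_pre", "control_post",
                     "intervention_pre", "intervention_post")

COMPLETENESS_METRICS <- c("weight", "length", "corrected_age",
                          "lhfa", "wflh", "wfa", "interval_growth")
CONCORDANCE_METRICS <- c("lhfa", "wflh", "wfa", "interval_growth")

exposure_group <- function(arm, period) {
  ifelse(is.na(arm) | is.na(period), NA_character_, paste(arm, period, sep = "_"))
}

#' Apply the study's cohort filters to a visit table
#'
#' Drops (1) visits with no matching child record (logged as issues),
#' (2) visits outside both study periods (`period` missing), and
#' (3) post-period visits of children who enrolled during the
#' pre-intervention period, which would contaminate the exposure groups.
#' Optionally restricts visits to standard growth-assessment visits on or
#' after a cutover date; this restriction applies only to the
#' length/height-for-age completeness metric and is off by default.
#'
#' @param visits,children visit and child tables.
#' @param lhfa_cutover_date `NULL` (default) or a `Date`: when set,
#'   visits on/after this date that are not `standard_growth` are marked
#'   `lhfa_excluded` (used by [audit_completeness()]).
#' @return The filtered visit table with an added `group` column
#'   (arm x period) and, when a cutover is set, `lhfa_excluded`; dropped
#'   rows are summarised in `attr(, "issues")`.
#' @export
apply_cohort_filters <- function(visits, children, lhfa_cutover_date = NULL) {
  issues <- character(0)
  orphan <- !visits$child_id %in% children$child_id
  if (any(orphan)) {
    issues <- c(issues, sprintf("dropped %d orphan visit(s) with no child record",
                                sum(orphan)))
    visits <- visits[!orphan, , drop = FALSE]
  }
  ch <- children[match(visits$child_id, children$child_id), , drop = FALSE]
  out_of_window <- is.na(visits$period)
  if (any(out_of_window)) {
    issues <- c(issues, sprintf("dropped %d visit(s) outside both study periods",
                                sum(out_of_window)))
  }
  contaminated <- !out_of_window & visits$period == "post" &
    !is.na(ch$enrollment_period) & ch$enrollment_period == "pre"
  if (any(contaminated)) {
    issues <- c(issues, sprintf(
      "dropped %d contaminated post-period visit(s) from pre-period enrollees",
      sum(contaminated)))
  }
  keep <- !out_of_window & !contaminated
  visits <- visits[keep, , drop = FALSE]
  ch <- ch[keep, , drop = FALSE]
  visits$group <- exposure_group(ch$arm, visits$period)
  if (!is.null(lhfa_cutover_date)) {
    visits$lhfa_excluded <- visits$visit_date >= as.Date(lhfa_cutover_date) &
      visits$visit_type != "standard_growth"
  }
  rownames(visits) <- NULL
  attr(visits, "issues") <- issues
  visits
}

nurse_recorded <- function(visits, metric) {
  switch(metric,
    weight = !is.na(visits$weight_g),
    length = !is.na(visits$length_cm),
    corrected_age = visits$nurse_corrected_age_recorded %in% TRUE,
    lhfa = !is.na(visits$nurse_lhfa),
    wflh = !is.na(visits$nurse_wflh),
    wfa = !is.na(visits$nurse_wfa),
    interval_growth = !is.na(visits$nurse_interval_growth_category) |
      !is.na(visits$nurse_interval_growth_value))
}

#' Completeness of nurse growth-monitoring recording
#'
#' For each exposure group and metric, the share of visits where the
#' nurse recorded a response. A recorded "not applicable" counts as
#' complete, and interval growth counts as complete whether recorded as
#' a category or as a continuous g/day value. The corrected-age metric
#' is tallied among visits of preterm children only. Percentages are
#' rounded half-up to integers.
#'
#' @param visits filtered visit table (see [apply_cohort_filters()];
#'   must carry `group`).
#' @param children child table.
#' @return Long-format data frame `group`, `metric`, `numerator`,
#'   `denominator`, `percent` (NA when the denominator is 0), of class
#'   `completeness_report`.
#' @export
audit_completeness <- function(visits, children) {
  ch <- children[match(visits$child_id, children$child_id), , drop = FALSE]
  preterm <- is_preterm(ch$gestational_age_weeks, ch$referred_as_preterm)
  rows <- list()
  for (g in EXPOSURE_GROUPS) {
    in_g <- visits$group %in% g
    for (m in COMPLETENESS_METRICS) {
      denom_sel <- in_g
      if (m == "corrected_age") denom_sel <- denom_sel & preterm %in% TRUE
      if (m == "lhfa" && !is.null(visits$lhfa_excluded)) {
        denom_sel <- denom_sel & !visits$lhfa_excluded
      }
      den <- sum(denom_sel)
      num <- sum(nurse_recorded(visits, m) & denom_sel)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, numerator = num, denominator = den,
        percent = if (den > 0) round_half_up(100 * num / den) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("completeness_report", "data.frame")
  out
}

# Gold-standard class and validability for one concordance metric.
gold_for_metric <- function(assessed, metric) {
  switch(metric,
    lhfa = assessed$class_lhfa,
    wflh = assessed$class_wflh,
    wfa = assessed$class_wfa,
    interval_growth = assessed$class_interval)
}

nurse_for_metric <- function(assessed, metric) {
  switch(metric,
    lhfa = assessed$nurse_lhfa,
    wflh = assessed$nurse_wflh,
    wfa = assessed$nurse_wfa,
    interval_growth = assessed$nurse_interval_growth_category)
}

#' Concordance of nurse classifications with the gold standard
#'
#' For each metric the denominator is the set of visits where the nurse
#' recorded that metric. An entry is concordant when the nurse-recorded
#' category (`normal` / `moderate` / `severe` / `not_applicable`, or
#' `adequate` / `inadequate` / `not_applicable` for interval growth)
#' equals the class recomputed from the raw measurements under the
#' standardized definitions. It is discordant when (1) the categories
#' differ, (2) the raw data are insufficient to validate the response
#' (the gold class is uncomputable), or (3) a recorded measurement is
#' implausible -- any raw z-score beyond +/-5.
#'
#' Interval growth is special-cased: each child's first visit is
#' excluded (no usable previous weight exists in the record system), and
#' a continuous g/day entry with no category counts as concordant iff
#' classifying that value against the child's age band reproduces the
#' gold adequate/inadequate call.
#'
#' @param assessed output of [assess_cohort()] on filtered visits (must
#'   carry `group` and the nurse columns).
#' @return Long-format data frame `group`, `metric`, `matching`,
#'   `not_matching`, `percent_matching`, of class `concordance_report`.
#' @export
audit_concordance <- function(assessed) {
  rows <- list()
  for (g in EXPOSURE_GROUPS) {
    in_g <- assessed$group %in% g
    for (m in CONCORDANCE_METRICS) {
      sel <- in_g & nurse_recorded(assessed, m)
      if (m == "interval_growth") sel <- sel & !assessed$is_first_visit
      n_assessed <- sum(sel)
      match_flag <- concordant(assessed[sel, , drop = FALSE], m)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m,
        matching = sum(match_flag), not_matching = sum(!match_flag),
        percent_matching = if (n_assessed > 0)
          round_half_up(100 * mean(match_flag)) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("concordance_report", "data.frame")
  out
}

concordant <- function(rows, metric) {
  if (nrow(rows) == 0L) return(logical(0))
  gold <- gold_for_metric(rows, metric)
  nurse <- nurse_for_metric(rows, metric)
  # Rule (2): insufficient data -- gold class uncomputable from raw inputs.
  insufficient <- is.na(gold)
  # Rule (3): implausible measurements, z-score metrics only.
  implausible <- if (metric == "interval_growth") FALSE else rows$implausible
  ok <- !insufficient & !implausible & !is.na(nurse) & nurse == gold
  if (metric == "interval_growth") {
    # Continuous-only entries: concordant iff the recorded g/day value,
    # put through the age band, reproduces the gold classification.
    cont <- is.na(nurse) & !is.na(rows$nurse_interval_growth_value)
    if (any(cont)) {
      implied <- classify_interval_growth(
        rows$nurse_interval_growth_value[cont],
        rows$corrected_age_days[cont],
        prev_weight_present = TRUE)
      ok[cont] <- !insufficient[cont] & gold[cont] %in% c("adequate", "inadequate") &
        implied == gold[cont]
    }
  }
  ok
}
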