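# Child-level nutritional status at target corrected ages: visit
# selection, outcome flags and prevalence by exposure group.

OUTCOME_NAMES <- c("stunted", "wasted", "underweight", "inadequate_growth")

#' Select the visit closest to a target corrected age
#'
#' Returns the row index (within `assessed_child`) of the visit whose
#' corrected age is nearest the target, provided it lies within one
#' month (30.4375 days) of it; ties between two equidistant visits go to
#' the earlier visit.
#'
#' @param assessed_child assessment rows for one child (must carry
#'   `corrected_age_days` and `visit_date`).
#' @param target_age_months target corrected age in months (2 or 6 in
#'   the evaluation; any value accepted).
#' @return Integer index, or `NA_integer_` when no visit qualifies.
#' @export
select_target_visit <- function(assessed_child, target_age_months) {
  target <- target_age_months * DAYS_PER_MONTH
  dist <- abs(assessed_child$corrected_age_days - target)
  ok <- which(!is.na(dist) & dist <= DAYS_PER_MONTH)
  if (length(ok) == 0L) return(NA_integer_)
  best <- min(dist[ok])
  cand <- ok[dist[ok] == best]
  if (length(cand) > 1L) cand <- cand[order(assessed_child$visit_date[cand])][1L]
  cand
}

#' Child-level nutritional outcomes at target corrected ages
#'
#' For every child enrolled before 2 months corrected age, selects the
#' closest visit within one month of each target corrected age and
#' derives the outcome flags: stunted (length/height-for-age z < -2),
#' wasted (weight-for-length/height z < -2), underweight
#' (weight-for-age z < -2) and inadequate interval growth. Flags are
#' missing when the selected visit's data are incomplete for that
#' indicator or implausible (any raw z beyond +/-5); the interval-growth
#' flag is additionally missing when the previous weight is missing.
#'
#' @param assessed output of [assess_cohort()] on filtered visits
#'   (carrying `group`).
#' @param children child table.
#' @param target_age_months numeric vector of target ages (default
#'   `c(2, 6)`).
#' @return Data frame, one row per child x target age with a qualifying
#'   visit: `child_id`, `target_age_months`, `group`,
#'   `selected_visit_date`, `corrected_age_days` and the four flags.
#' @export
cohort_outcomes <- function(assessed, children, target_age_months = c(2, 6)) {
  ch <- children[match(assessed$child_id, children$child_id), , drop = FALSE]
  enrol_age <- corrected_age(ch$birth_date, ch$enrollment_date,
                             ch$gestational_age_weeks, ch$referred_as_preterm)
  eligible <- enrol_age$corrected_age_days < 2 * DAYS_PER_MONTH
  assessed <- assessed[eligible %in% TRUE, , drop = FALSE]

  rows <- list()
  for (cid in unique(assessed$child_id)) {
    av <- assessed[assessed$child_id == cid, , drop = FALSE]
    for (tgt in target_age_months) {
      i <- select_target_visit(av, tgt)
      if (is.na(i)) next
      v <- av[i, , drop = FALSE]
      excl <- v$implausible %in% TRUE
      flag <- function(z) if (excl || is.na(z)) NA else z < -2
      rows[[length(rows) + 1L]] <- data.frame(
        child_id = cid, target_age_months = tgt, group = v$group,
        selected_visit_date = v$visit_date,
        corrected_age_days = v$corrected_age_days,
        stunted = flag(v$z_lhfa),
        wasted = flag(v$z_wflh),
        underweight = flag(v$z_wfa),
        inadequate_growth = if (excl || !v$class_interval %in%
                                c("adequate", "inadequate")) NA
                            else v$class_interval == "inadequate",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(child_id = character(0), target_age_months = numeric(0),
                      group = character(0), selected_visit_date = as.Date(character(0)),
                      corrected_age_days = integer(0), stunted = logical(0),
                      wasted = logical(0), underweight = logical(0),
                      inadequate_growth = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prevalence of nutritional outcomes by exposure group
#'
#' Tallies each outcome over the child-level outcome table. Denominators
#' exclude children whose flag is missing (incomplete or implausible
#' data; for interval growth, also a missing previous weight).
#' Percentages are rounded half-up to integers.
#'
#' @param outcomes output of [cohort_outcomes()].
#' @return Long-format data frame `target_age_months`, `group`,
#'   `outcome`, `numerator`, `denominator`, `percent` (NA when the
#'   denominator is 0).
#' @export
outcome_prevalence <- function(outcomes) {
  rows <- list()
  for (tgt in sort(unique(outcomes$target_age_months))) {
    for (g in EXPOSURE_GROUPS) {
      sel <- outcomes$target_age_months == tgt & outcomes$group %in% g
      for (oc in OUTCOME_NAMES) {
        flags <- outcomes[[oc]][sel]
        den <- sum(!is.na(flags))
        num <- sum(flags, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          target_age_months = tgt, group = g, outcome = oc,
          numerator = num, denominator = den,
          percent = if (den > 0) round_half_up(100 * num / den) else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
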