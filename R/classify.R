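# The rule-based classification layer: nutritional categories from
# z-scores, interval weight gain and its age-banded adequacy thresholds,
# and the traffic-light colour coding shown to providers.

# Interval-growth adequacy bands: lower age bound (months, inclusive),
# upper bound (exclusive) and the minimum adequate rate in g/day.
INTERVAL_BANDS <- data.frame(
  lo_mo = c(0, 3, 6, 8, 12, 16),
  hi_mo = c(3, 6, 8, 12, 16, 24),
  min_g_per_day = c(20, 15, 10, 6, 5, 4)
)

#' Classify an anthropometric z-score
#'
#' Applies the clinic protocol's standardized definitions. Not-applicable
#' conditions are checked first, from the raw inputs:
#' \itemize{
#'   \item length/height-for-age: corrected age < 0 days, or
#'     length/height < 42 cm;
#'   \item weight-for-length/height: length/height < 45 cm, corrected
#'     age < 0 days, or weight < 1.6 kg;
#'   \item weight-for-age: corrected age < 0 days, or weight < 1.4 kg.
#' }
#' Otherwise the z-score maps to `normal` (z >= -2), `moderate`
#' (-3 <= z < -2) or `severe` (z < -3); both lower bounds are closed, so
#' z = -2 is normal and z = -3 moderate.
#'
#' @param indicator `"length_for_age"`, `"weight_for_length"` or
#'   `"weight_for_age"`.
#' @param z z-score vector (NA allowed where a not-applicable condition
#'   holds or inputs were missing).
#' @param corrected_age_days integer vector.
#' @param weight_kg,length_cm measurement vectors (kg, cm).
#' @return character vector in `normal`, `moderate`, `severe`,
#'   `not_applicable`; NA when no NA condition holds but `z` is
#'   uncomputable.
#' @export
classify_zscore <- function(indicator, z, corrected_age_days,
                            weight_kg = NA_real_, length_cm = NA_real_) {
  indicator <- match.arg(indicator, INDICATORS)
  n <- max(length(z), length(corrected_age_days), length(weight_kg), length(length_cm))
  z <- rep_len(z, n)
  age <- rep_len(corrected_age_days, n)
  wt <- rep_len(weight_kg, n)
  len <- rep_len(length_cm, n)
  na_cond <- switch(indicator,
    length_for_age    = (age < 0) %in% TRUE | (len < 42) %in% TRUE,
    weight_for_length = (len < 45) %in% TRUE | (age < 0) %in% TRUE | (wt < 1.6) %in% TRUE,
    weight_for_age    = (age < 0) %in% TRUE | (wt < 1.4) %in% TRUE)
  out <- ifelse(na_cond, "not_applicable",
         ifelse(is.na(z), NA_character_,
         ifelse(z >= -2, "normal",
         ifelse(z >= -3, "moderate", "severe"))))
  out
}

#' Age-banded interval-growth adequacy threshold
#'
#' @param corrected_age_days integer vector.
#' @return Minimum adequate weight gain in g/day for the corrected-age
#'   band (`[0,3)` mo: 20; `[3,6)`: 15; `[6,8)`: 10; `[8,12)`: 6;
#'   `[12,16)`: 5; `[16,24)`: 4), or NA outside `[0, 24)` months.
#' @export
interval_growth_threshold <- function(corrected_age_days) {
  mo <- corrected_age_days / DAYS_PER_MONTH
  idx <- findInterval(mo, c(INTERVAL_BANDS$lo_mo, 24))
  ok <- !is.na(mo) & mo >= 0 & idx >= 1 & idx <= nrow(INTERVAL_BANDS)
  out <- rep(NA_real_, length(mo))
  out[ok] <- INTERVAL_BANDS$min_g_per_day[idx[ok]]
  out
}

#' Interval weight gain between two weighed visits
#'
#' @param weight_now_g,weight_prev_g weights in grams.
#' @param days_between days separating the two measurements (>= 1).
#' @return Signed average daily gain in g/day (negative for weight loss);
#'   NA when either weight is missing.
#' @export
interval_growth_rate <- function(weight_now_g, weight_prev_g, days_between) {
  if (any(!is.na(days_between) & days_between < 1)) {
    stop_pdc("days between visits must be >= 1", class = "pdc_value_error")
  }
  (weight_now_g - weight_prev_g) / days_between
}

#' Classify interval growth
#'
#' Adequate when the rate meets the age band's threshold
#' (see [interval_growth_threshold()]); the comparison is `>=`, so a rate
#' exactly at the threshold is adequate. Not applicable when corrected
#' age is negative or at/after 24 months, or when the previous weight is
#' missing.
#'
#' @param rate_g_per_day numeric vector.
#' @param corrected_age_days integer vector.
#' @param prev_weight_present logical vector.
#' @return character vector in `adequate`, `inadequate`,
#'   `not_applicable`.
#' @export
classify_interval_growth <- function(rate_g_per_day, corrected_age_days,
                                     prev_weight_present = !is.na(rate_g_per_day)) {
  n <- max(length(rate_g_per_day), length(corrected_age_days),
           length(prev_weight_present))
  rate <- rep_len(rate_g_per_day, n)
  age <- rep_len(corrected_age_days, n)
  prev <- rep_len(as.logical(prev_weight_present), n)
  thr <- interval_growth_threshold(age)
  na_cond <- is.na(age) | age < 0 | age >= 24 * DAYS_PER_MONTH | !(prev %in% TRUE)
  ifelse(na_cond, "not_applicable",
  ifelse(is.na(rate), NA_character_,
  ifelse(rate >= thr, "adequate", "inadequate")))
}

#' Traffic-light colour for a classification
#'
#' The provider-facing colour coding: green for normal nutritional status
#' or adequate growth, yellow for moderate malnutrition, red for severe
#' malnutrition or inadequate growth.
#'
#' @param class character vector of classifications.
#' @return character vector in `green`, `yellow`, `red`; NA for
#'   `not_applicable` or missing.
#' @export
classification_colour <- function(class) {
  unname(c(normal = "green", adequate = "green",
           moderate = "yellow",
           severe = "red", inadequate = "red")[class])
}
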