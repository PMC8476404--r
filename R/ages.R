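# Corrected age and perinatal risk flags.

#' Is a child preterm?
#'
#' A child is preterm if gestational age at birth is below 37 completed
#' weeks, or if gestational age is missing but the child was referred to
#' the clinic as preterm.
#'
#' @param gestational_age_weeks numeric vector (weeks; NA when
#'   undocumented).
#' @param referred_as_preterm logical vector.
#' @return logical vector.
#' @export
is_preterm <- function(gestational_age_weeks, referred_as_preterm = FALSE) {
  n <- max(length(gestational_age_weeks), length(referred_as_preterm))
  ga <- rep_len(gestational_age_weeks, n)
  ref <- rep_len(as.logical(referred_as_preterm), n)
  ifelse(!is.na(ga), ga < 37, ref %in% TRUE)
}

#' Is a child low birthweight?
#'
#' @param birthweight_g numeric vector of birthweights in grams.
#' @return logical; `TRUE` below 2500 g, NA when missing.
#' @export
is_lbw <- function(birthweight_g) {
  birthweight_g < 2500
}

#' Is a child small for gestational age?
#'
#' Compares birthweight against the 10th percentile for gestational age
#' and sex from a user-supplied percentile reference (for real analyses,
#' the INTERGROWTH-21st newborn standard; a synthetic fixture ships for
#' tests). The 10th-percentile weight is linearly interpolated in
#' gestational age.
#'
#' @param gestational_age_weeks,sex,birthweight_g vectors describing the
#'   children (recycled to a common length).
#' @param percentile_table data frame with columns `sex`
#'   (`male`/`female`), `ga_weeks`, `p10_weight_g`.
#' @return logical; NA when gestational age or birthweight is missing or
#'   out of the table's span.
#' @export
is_sga <- function(gestational_age_weeks, sex, birthweight_g, percentile_table) {
  req <- c("sex", "ga_weeks", "p10_weight_g")
  if (!all(req %in% names(percentile_table))) {
    stop_pdc("percentile table must have columns %s", paste(req, collapse = ", "),
             class = "pdc_schema_error")
  }
  n <- max(length(gestational_age_weeks), length(sex), length(birthweight_g))
  ga <- rep_len(gestational_age_weeks, n)
  sx <- rep_len(as.character(sex), n)
  bw <- rep_len(birthweight_g, n)
  out <- rep(NA, n)
  for (s in unique(stats::na.omit(sx))) {
    tab <- percentile_table[percentile_table$sex == s, , drop = FALSE]
    tab <- tab[order(tab$ga_weeks), , drop = FALSE]
    sel <- which(sx == s & !is.na(ga) & !is.na(bw))
    if (length(sel) == 0L || nrow(tab) == 0L) next
    p10 <- stats::approx(tab$ga_weeks, tab$p10_weight_g, xout = ga[sel], rule = 1L)$y
    out[sel] <- bw[sel] < p10
  }
  out
}

#' Corrected age at a visit
#'
#' Chronological age minus the days born before 40 weeks' gestation:
#' preterm infants (< 37 weeks) with a documented gestational age `g`
#' get `chronological - round(7 * (40 - g))` days, which may be negative
#' before the due date. Term children keep their chronological age.
#' Preterm children whose gestational age is undocumented fall back to
#' chronological age, flagged `correction_unavailable`.
#'
#' @param birth_date,visit_date `Date` vectors (recycled).
#' @param gestational_age_weeks numeric (weeks, possibly fractional for
#'   weeks+days); NA when undocumented.
#' @param referred_as_preterm logical, used only to flag the fallback.
#' @return A data frame with columns `chronological_age_days`,
#'   `corrected_age_days` (integer, possibly negative) and
#'   `correction_unavailable` (logical).
#' @export
corrected_age <- function(birth_date, visit_date, gestational_age_weeks,
                          referred_as_preterm = FALSE) {
  n <- max(length(birth_date), length(visit_date),
           length(gestational_age_weeks), length(referred_as_preterm))
  bd <- rep_len(as.Date(birth_date), n)
  vd <- rep_len(as.Date(visit_date), n)
  ga <- rep_len(gestational_age_weeks, n)
  ref <- rep_len(as.logical(referred_as_preterm), n)
  if (any(!is.na(bd) & !is.na(vd) & vd < bd)) {
    stop_pdc("visit date precedes birth date", class = "pdc_value_error")
  }
  chron <- days_between(vd, bd)
  preterm <- is_preterm(ga, ref)
  weeks_early_days <- as.integer(round_half_up(7 * (40 - ga)))
  corrected <- ifelse(preterm & !is.na(ga), chron - weeks_early_days, chron)
  data.frame(chronological_age_days = chron,
             corrected_age_days = as.integer(corrected),
             correction_unavailable = preterm & is.na(ga))
}
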