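# Gold-standard growth assessment of clinic visits: ages, z-scores,
# interval growth, protocol classifications and colours, plausibility.

# Threshold beyond which a raw (unrestricted) z-score marks the visit's
# measurements as implausible data entry.
IMPLAUSIBLE_Z <- 5

ref_for <- function(references, indicator, sex) {
  tab <- references[[indicator]][[sex]]
  if (is.null(tab)) {
    stop_pdc("no %s reference loaded for sex '%s'", indicator, sex,
             class = "pdc_value_error")
  }
  tab
}

#' Assess a single clinic visit
#'
#' Computes the gold-standard growth assessment the mHealth tool
#' automates for one visit: chronological and corrected age, the three
#' anthropometric z-scores (length/height-for-age, weight-for-length/
#' height, weight-for-age) against the loaded references, interval weight
#' gain since the previous weighed visit, the protocol classifications
#' with their colour codes, and an implausibility flag raised when any
#' raw z-score lies beyond +/-5.
#'
#' Age-indexed z-scores are evaluated at the corrected age; weight-based
#' indicators use the restricted adjustment beyond +/-3 z. A z-score is
#' left undefined (NA) when its measurements are missing or its index
#' falls outside the reference span.
#'
#' @param child one-row data frame (or list) with `birth_date`, `sex`,
#'   `gestational_age_weeks`, `referred_as_preterm`.
#' @param visit one-row data frame (or list) with `visit_date`,
#'   `weight_g`, `length_cm`.
#' @param prev_visit the most recent earlier visit with a recorded
#'   weight (`visit_date`, `weight_g`), or `NULL` for a first visit.
#' @param references a reference set (see [synthetic_reference()]).
#' @return One-row data frame: ages, `z_lhfa`, `z_wflh`, `z_wfa` (raw
#'   z in `z_*_raw`), `interval_growth_g_per_day`, classes
#'   `class_lhfa`, `class_wflh`, `class_wfa`, `class_interval`, colours
#'   `colour_*`, and `implausible`.
#' @export
assess_visit <- function(child, visit, prev_visit = NULL, references) {
  child <- as.list(child)
  visit <- as.list(visit)
  if (is.null(child$birth_date) || is.na(child$birth_date) ||
      is.null(child$sex) || is.na(child$sex) || !child$sex %in% SEXES) {
    stop_pdc("child record needs a birth date and a known sex",
             class = "pdc_validation_error")
  }
  ages <- corrected_age(child$birth_date, visit$visit_date,
                        child$gestational_age_weeks %||% NA_real_,
                        child$referred_as_preterm %||% FALSE)
  age <- ages$corrected_age_days
  wt_kg <- (visit$weight_g %||% NA_real_) / 1000
  len <- visit$length_cm %||% NA_real_

  zs <- function(ind, y, idx) {
    tab <- ref_for(references, ind, child$sex)
    raw <- reference_zscore(tab, y, idx, restricted = FALSE)
    adj <- reference_zscore(tab, y, idx, restricted = "auto")
    c(raw = raw, adj = adj)
  }
  z_lhfa <- zs("length_for_age", len, age)
  z_wfa <- zs("weight_for_age", wt_kg, age)
  z_wflh <- zs("weight_for_length", wt_kg, len)

  rate <- NA_real_
  prev_present <- FALSE
  if (!is.null(prev_visit) && !is.na(as.list(prev_visit)$weight_g %||% NA_real_) &&
      !is.na(visit$weight_g %||% NA_real_)) {
    prev_visit <- as.list(prev_visit)
    gap <- days_between(visit$visit_date, prev_visit$visit_date)
    rate <- interval_growth_rate(visit$weight_g, prev_visit$weight_g, gap)
    prev_present <- TRUE
  }

  cls_l <- classify_zscore("length_for_age", z_lhfa["adj"], age, wt_kg, len)
  cls_wl <- classify_zscore("weight_for_length", z_wflh["adj"], age, wt_kg, len)
  cls_wa <- classify_zscore("weight_for_age", z_wfa["adj"], age, wt_kg, len)
  cls_iv <- classify_interval_growth(rate, age, prev_present)

  raws <- c(z_lhfa["raw"], z_wflh["raw"], z_wfa["raw"])
  implausible <- any(abs(raws) > IMPLAUSIBLE_Z, na.rm = TRUE)

  data.frame(
    chronological_age_days = ages$chronological_age_days,
    corrected_age_days = age,
    correction_unavailable = ages$correction_unavailable,
    z_lhfa = unname(z_lhfa["adj"]), z_lhfa_raw = unname(z_lhfa["raw"]),
    z_wflh = unname(z_wflh["adj"]), z_wflh_raw = unname(z_wflh["raw"]),
    z_wfa = unname(z_wfa["adj"]), z_wfa_raw = unname(z_wfa["raw"]),
    interval_growth_g_per_day = rate,
    class_lhfa = cls_l, class_wflh = cls_wl, class_wfa = cls_wa,
    class_interval = cls_iv,
    colour_lhfa = classification_colour(cls_l),
    colour_wflh = classification_colour(cls_wl),
    colour_wfa = classification_colour(cls_wa),
    colour_interval = classification_colour(cls_iv),
    implausible = implausible,
    stringsAsFactors = FALSE)
}

#' Assess every visit in a cohort
#'
#' Runs [assess_visit()] over a visit table, linking each visit to the
#' child's most recent earlier visit with a recorded weight (the "weight
#' at last visit" used for interval growth) and flagging each child's
#' first visit. Visits whose child record is missing, lacks a birth date
#' or has an unknown sex are skipped with a logged issue.
#'
#' @param children child table (see [read_children()] for the column
#'   dictionary).
#' @param visits visit table (see [read_visits()]).
#' @param references a reference set.
#' @return The visit table augmented with the assessment columns of
#'   [assess_visit()] plus `is_first_visit`, one row per retained visit;
#'   skipped visits are recorded in `attr(, "issues")`.
#' @export
assess_cohort <- function(children, visits, references) {
  issues <- character(0)
  keep <- visits$child_id %in% children$child_id
  if (any(!keep)) {
    issues <- c(issues, sprintf("visit row %d: unknown child_id '%s', skipped",
                                which(!keep), visits$child_id[!keep]))
  }
  visits <- visits[keep, , drop = FALSE]
  ch_idx <- match(visits$child_id, children$child_id)
  bad_child <- is.na(children$birth_date[ch_idx]) |
    is.na(children$sex[ch_idx]) | !children$sex[ch_idx] %in% SEXES
  if (any(bad_child)) {
    issues <- c(issues, sprintf(
      "visit row for child '%s': missing birth date or unknown sex, skipped",
      visits$child_id[bad_child]))
    visits <- visits[!bad_child, , drop = FALSE]
  }
  ord <- order(visits$child_id, visits$visit_date)
  visits <- visits[ord, , drop = FALSE]

  out <- vector("list", nrow(visits))
  prev_by_child <- list()
  first_by_child <- list()
  is_first <- logical(nrow(visits))
  for (i in seq_len(nrow(visits))) {
    v <- visits[i, , drop = FALSE]
    cid <- as.character(v$child_id)
    ch <- children[children$child_id == cid, , drop = FALSE][1L, ]
    is_first[i] <- is.null(first_by_child[[cid]])
    first_by_child[[cid]] <- FALSE
    out[[i]] <- assess_visit(ch, v, prev_by_child[[cid]], references)
    if (!is.na(v$weight_g)) prev_by_child[[cid]] <- v
  }
  res <- cbind(visits, do.call(rbind, out), is_first_visit = is_first)
  rownames(res) <- NULL
  attr(res, "issues") <- issues
  res
}
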