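# Ingest and validation of EMR extract tables, and delimited report
# output. File dialect: comma-separated, UTF-8, header row required,
# missing values as empty fields, dates ISO-8601, weights in grams.

CHILD_COLUMNS <- c("child_id", "birth_date", "gestational_age_weeks",
                   "referred_as_preterm", "birthweight_g", "enrollment_date",
                   "sex", "facility_id", "facility_type", "arm")
VISIT_COLUMNS <- c("child_id", "visit_date", "visit_type", "weight_g",
                   "length_cm", "nurse_corrected_age_recorded", "nurse_lhfa",
                   "nurse_wflh", "nurse_wfa", "nurse_interval_growth")

read_delim_checked <- function(path, required, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), strip.white = TRUE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_pdc("%s file %s is missing required column(s): %s", what, path,
             paste(missing_cols, collapse = ", "), class = "pdc_schema_error")
  }
  df
}

parse_date <- function(x, field, issues) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad) > 0L) {
    issues$log <- c(issues$log, sprintf("row %d: unparseable %s '%s'",
                                        bad, field, x[bad]))
  }
  d
}

new_issues <- function() new.env(parent = emptyenv())

parse_logical <- function(x) {
  x <- tolower(as.character(x))
  ifelse(x %in% c("true", "t", "1"), TRUE,
  ifelse(x %in% c("false", "f", "0"), FALSE, NA))
}

#' Read a child table
#'
#' Column dictionary: `child_id`; `birth_date`, `enrollment_date`
#' (ISO-8601); `gestational_age_weeks` (weeks, decimals allowed for
#' weeks+days); `referred_as_preterm` (TRUE/FALSE or 1/0);
#' `birthweight_g` (grams); `sex` (`male`/`female`, `m`/`f` accepted);
#' `facility_id`; `facility_type` (`hospital`/`health_centre`); `arm`
#' (`control`/`intervention`). Missing values are empty fields.
#'
#' @param path CSV file path.
#' @return Data frame with parsed columns; row-level problems in
#'   `attr(, "issues")`.
#' @export
read_children <- function(path) {
  df <- read_delim_checked(path, CHILD_COLUMNS, "children")
  iss <- new_issues(); iss$log <- character(0)
  df$birth_date <- parse_date(df$birth_date, "birth_date", iss)
  df$enrollment_date <- parse_date(df$enrollment_date, "enrollment_date", iss)
  df$sex <- c(m = "male", f = "female", male = "male", female = "female")[
    tolower(as.character(df$sex))]
  df$referred_as_preterm <- parse_logical(df$referred_as_preterm)
  df$gestational_age_weeks <- as.numeric(df$gestational_age_weeks)
  df$birthweight_g <- as.numeric(df$birthweight_g)
  ga_bad <- which(!is.na(df$gestational_age_weeks) &
                  (df$gestational_age_weeks <= 20 | df$gestational_age_weeks >= 45))
  if (length(ga_bad) > 0L) {
    iss$log <- c(iss$log, sprintf(
      "row %d: gestational age %g weeks outside (20, 45), set missing",
      ga_bad, df$gestational_age_weeks[ga_bad]))
    df$gestational_age_weeks[ga_bad] <- NA_real_
  }
  attr(df, "issues") <- iss$log
  df
}

#' Read a visit table
#'
#' Column dictionary: `child_id`; `visit_date` (ISO-8601); `visit_type`
#' (`standard_growth`/`other`); `weight_g` (grams); `length_cm`;
#' `nurse_corrected_age_recorded` (TRUE/FALSE or 1/0); `nurse_lhfa`,
#' `nurse_wflh`, `nurse_wfa` (`normal`/`moderate`/`severe`/
#' `not_applicable`, empty = not recorded); `nurse_interval_growth`
#' (one of `adequate`/`inadequate`/`not_applicable`, or a bare number
#' read as a continuous g/day entry, empty = not recorded). The raw
#' interval column is split into `nurse_interval_growth_category` and
#' `nurse_interval_growth_value`.
#'
#' @param path CSV file path.
#' @return Data frame with parsed columns; row-level problems in
#'   `attr(, "issues")`.
#' @export
read_visits <- function(path) {
  df <- read_delim_checked(path, VISIT_COLUMNS, "visits")
  iss <- new_issues(); iss$log <- character(0)
  df$visit_date <- parse_date(df$visit_date, "visit_date", iss)
  df$weight_g <- as.numeric(df$weight_g)
  df$length_cm <- as.numeric(df$length_cm)
  df$nurse_corrected_age_recorded <- parse_logical(df$nurse_corrected_age_recorded)
  for (col in c("nurse_lhfa", "nurse_wflh", "nurse_wfa")) {
    df[[col]] <- match_arg_chr(df[[col]], ZSCORE_CLASSES, col)
  }
  raw <- as.character(df$nurse_interval_growth)
  val <- suppressWarnings(as.numeric(raw))
  cat_ <- ifelse(is.na(val), raw, NA_character_)
  cat_ <- match_arg_chr(cat_, INTERVAL_CLASSES, "nurse_interval_growth")
  df$nurse_interval_growth_category <- cat_
  df$nurse_interval_growth_value <- val
  df$nurse_interval_growth <- NULL
  neg <- which((df$weight_g <= 0) %in% TRUE | (df$length_cm <= 0) %in% TRUE)
  if (length(neg) > 0L) {
    iss$log <- c(iss$log, sprintf("row %d: non-positive measurement, set missing", neg))
    df$weight_g[df$weight_g <= 0] <- NA_real_
    df$length_cm[df$length_cm <= 0] <- NA_real_
  }
  attr(df, "issues") <- iss$log
  df
}

#' Load and validate an EMR extract
#'
#' Reads the child and visit tables, links them, labels study periods,
#' and flags (without dropping) visits whose measurements are
#' implausible against the references -- any raw z-score beyond +/-5 --
#' as candidate data-entry errors.
#'
#' @param children_path,visits_path CSV paths.
#' @param references a reference set, used for the plausibility screen;
#'   `NULL` skips it.
#' @param periods study windows (see [default_periods()]).
#' @return `list(children, visits, issues)`; `visits` gains `period`
#'   and, when screened, `flag_implausible`.
#' @export
load_and_validate <- function(children_path, visits_path,
                              references = NULL,
                              periods = default_periods()) {
  children <- read_children(children_path)
  visits <- read_visits(visits_path)
  issues <- c(paste0("children: ", attr(children, "issues")),
              paste0("visits: ", attr(visits, "issues")))
  issues <- issues[!issues %in% c("children: ", "visits: ")]
  orphan <- !visits$child_id %in% children$child_id
  if (any(orphan)) {
    issues <- c(issues, sprintf("visits: row %d references unknown child '%s'",
                                which(orphan), visits$child_id[orphan]))
  }
  lab <- assign_periods(children, visits, periods)
  children <- lab$children; visits <- lab$visits
  if (!is.null(references)) {
    assessed <- assess_cohort(children, visits, references)
    key_v <- paste(visits$child_id, visits$visit_date)
    key_a <- paste(assessed$child_id, assessed$visit_date)
    visits$flag_implausible <- assessed$implausible[match(key_v, key_a)] %in% TRUE
    n_bad <- sum(visits$flag_implausible)
    if (n_bad > 0L) {
      issues <- c(issues, sprintf(
        "visits: %d visit(s) flagged implausible (raw z beyond +/-%d)",
        n_bad, IMPLAUSIBLE_Z))
    }
  }
  list(children = children, visits = visits, issues = issues)
}

#' Render an audit report in wide (publication-table) layout
#'
#' Pivots a long-format completeness or concordance report into a
#' metric-by-group table of `n (percent)` strings, mirroring the usual
#' audit-table presentation.
#'
#' @param report output of [audit_completeness()], [audit_concordance()]
#'   or [outcome_prevalence()].
#' @return Data frame, one row per metric/outcome, one column pair per
#'   exposure group.
#' @export
report_wide <- function(report) {
  key <- intersect(c("metric", "outcome"), names(report))[1]
  num_col <- intersect(c("numerator", "matching"), names(report))[1]
  pct_col <- intersect(c("percent", "percent_matching"), names(report))[1]
  extra <- intersect("target_age_months", names(report))
  ids <- unique(report[c(extra, key)])
  out <- ids
  for (g in EXPOSURE_GROUPS) {
    sub <- report[report$group == g, , drop = FALSE]
    m <- match(do.call(paste, ids), do.call(paste, sub[c(extra, key)]))
    out[[paste0(g, "_n")]] <- sub[[num_col]][m]
    out[[paste0(g, "_pct")]] <- sub[[pct_col]][m]
  }
  rownames(out) <- NULL
  out
}

#' Write a delimited report
#'
#' @param report any report data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, na = "")
  invisible(path)
}
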