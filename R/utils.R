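# Shared constants and small helpers.

#' Days per month used throughout the package
#'
#' Month-valued ages and thresholds (interval-growth bands, target ages,
#' the +/- 1 month visit-selection window) are converted to days at the
#' conventional 30.4375 days per month (365.25 / 12).
#'
#' @format A length-one numeric.
#' @export
DAYS_PER_MONTH <- 365.25 / 12

# Levels shared by nurse-recorded and gold-standard growth categories.
ZSCORE_CLASSES <- c("normal", "moderate", "severe", "not_applicable")
INTERVAL_CLASSES <- c("adequate", "inadequate", "not_applicable")

#' Round half away from zero
#'
#' Percentages in audit and prevalence reports are rounded half-up to
#' integers (so 64.5 prints as 65), unlike [base::round()], which rounds
#' half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded with ties going away from zero.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer day difference between two Date vectors.
days_between <- function(later, earlier) {
  as.integer(round(as.numeric(later) - as.numeric(earlier)))
}

stop_pdc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "pdcgrowth_error")))
}

match_arg_chr <- function(x, choices, what) {
  x <- as.character(x)
  if (!all(x %in% choices | is.na(x))) {
    stop_pdc("invalid %s: %s (expected one of %s)", what,
             paste(unique(setdiff(x, choices)), collapse = ", "),
             paste(choices, collapse = ", "),
             class = "pdc_value_error")
  }
  x
}
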