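# LMS reference machinery: tables, interpolation, z-scores and inverses.
#
# A growth reference in the LMS parameterisation stores, for each value of
# an index (age in days, or length in cm for weight-for-length), the
# Box-Cox power L, the median M and the coefficient of variation S. The
# z-score of a measurement y is then
#
#   z = ((y/M)^L - 1) / (L * S)        (L != 0)
#   z = log(y/M) / S                   (L == 0)
#
# Weight-based indicators additionally use the restricted ("fixed sd-gap")
# adjustment beyond +/-3 z, matching the WHO igrowup macros.

INDICATORS <- c("weight_for_age", "length_for_age", "weight_for_length")
SEXES <- c("male", "female")

#' Construct an LMS reference table
#'
#' @param indicator one of `"weight_for_age"`, `"length_for_age"`,
#'   `"weight_for_length"`.
#' @param sex `"male"` or `"female"`.
#' @param index numeric vector of strictly increasing index values: age in
#'   days for age-indexed indicators, length/height in cm for
#'   weight-for-length.
#' @param L,M,S numeric vectors of Box-Cox power, median and coefficient of
#'   variation, one value per index row. `M` and `S` must be positive.
#' @return An object of class `lms_table`: a data frame with columns
#'   `index`, `L`, `M`, `S` and attributes `indicator`, `sex`,
#'   `index_kind` (`"age_days"` or `"length_cm"`).
#' @seealso [interpolate_lms()], [lms_zscore()], [read_lms_table()]
#' @export
lms_table <- function(indicator, sex, index, L, M, S) {
  indicator <- match.arg(indicator, INDICATORS)
  sex <- match.arg(sex, SEXES)
  n <- length(index)
  if (n == 0L) {
    stop_pdc("an LMS table must have at least one row", class = "pdc_value_error")
  }
  if (length(L) != n || length(M) != n || length(S) != n) {
    stop_pdc("index, L, M, S must have equal length", class = "pdc_value_error")
  }
  if (any(!is.finite(index)) || any(index < 0)) {
    stop_pdc("index values must be finite and non-negative", class = "pdc_value_error")
  }
  if (is.unsorted(index, strictly = TRUE)) {
    stop_pdc("index values must be strictly increasing", class = "pdc_value_error")
  }
  if (any(M <= 0) || any(S <= 0)) {
    stop_pdc("M and S must be positive", class = "pdc_value_error")
  }
  out <- data.frame(index = as.numeric(index), L = as.numeric(L),
                    M = as.numeric(M), S = as.numeric(S))
  structure(out,
            indicator = indicator,
            sex = sex,
            index_kind = if (indicator == "weight_for_length") "length_cm" else "age_days",
            class = c("lms_table", "data.frame"))
}

#' @export
print.lms_table <- function(x, ...) {
  cat(sprintf("<lms_table> %s, %s; %d rows, index (%s) %g..%g\n",
              attr(x, "indicator"), attr(x, "sex"), nrow(x),
              attr(x, "index_kind"), min(x$index), max(x$index)))
  invisible(x)
}

#' Interpolate L, M, S at arbitrary index values
#'
#' Linear interpolation between the two bracketing reference rows; exact at
#' the rows themselves. No extrapolation: values outside the table's span
#' raise a range error (scalar input) or, with `strict = FALSE`, return NA.
#'
#' @param table an [lms_table()].
#' @param index_value numeric vector of ages (days) or lengths (cm).
#' @param strict if `TRUE` (default) out-of-range values are an error;
#'   otherwise they yield NA rows.
#' @return A data frame with columns `L`, `M`, `S`, one row per input.
#' @export
interpolate_lms <- function(table, index_value, strict = TRUE) {
  stopifnot(inherits(table, "lms_table"))
  lo <- table$index[1L]
  hi <- table$index[nrow(table)]
  out_of_range <- !is.na(index_value) & (index_value < lo | index_value > hi)
  if (strict && any(out_of_range)) {
    stop_pdc("index value %g outside the reference span [%g, %g] (%s)",
             index_value[which(out_of_range)[1L]], lo, hi, attr(table, "index_kind"),
             class = "pdc_range_error")
  }
  x <- ifelse(out_of_range, NA_real_, index_value)
  interp1 <- function(col) {
    if (nrow(table) == 1L) {
      ifelse(is.na(x), NA_real_, table[[col]][1L])
    } else {
      stats::approx(table$index, table[[col]], xout = x, rule = 1L)$y
    }
  }
  data.frame(L = interp1("L"), M = interp1("M"), S = interp1("S"))
}

#' LMS z-score of a measurement
#'
#' Computes the Box-Cox z-score of measurement `y` against LMS parameters,
#' optionally with the restricted adjustment used by the WHO igrowup macros
#' for weight-based indicators: beyond |z| = 3 the score is extended
#' linearly in measurement units using the gap between the 2 and 3 SD
#' cut-offs, i.e. for z > 3
#'
#'   z* = 3 + (y - SD3) / (SD3 - SD2)
#'
#' and symmetrically below -3. Inside [-3, 3] restricted and raw values
#' coincide.
#'
#' @param y positive measurement (same units as `M`). Vectorised.
#' @param L,M,S LMS parameters (recycled against `y`).
#' @param restricted logical; apply the restricted adjustment.
#' @return numeric z-score vector (NA where any input is NA).
#' @export
lms_zscore <- function(y, L, M, S, restricted = FALSE) {
  n <- max(length(y), length(L), length(M), length(S))
  y <- rep_len(as.numeric(y), n); L <- rep_len(as.numeric(L), n)
  M <- rep_len(as.numeric(M), n); S <- rep_len(as.numeric(S), n)
  if (any(!is.na(y) & y <= 0)) {
    stop_pdc("measurements must be positive", class = "pdc_domain_error")
  }
  z <- ifelse(L == 0, log(y / M) / S, ((y / M)^L - 1) / (L * S))
  if (!restricted) return(z)
  out <- z
  hi <- !is.na(z) & z > 3
  if (any(hi)) {
    sd3 <- lms_inverse_zscore(3, L[hi], M[hi], S[hi])
    sd2 <- lms_inverse_zscore(2, L[hi], M[hi], S[hi])
    out[hi] <- 3 + (y[hi] - sd3) / (sd3 - sd2)
  }
  lo <- !is.na(z) & z < -3
  if (any(lo)) {
    sd3n <- lms_inverse_zscore(-3, L[lo], M[lo], S[lo])
    sd2n <- lms_inverse_zscore(-2, L[lo], M[lo], S[lo])
    out[lo] <- -3 + (y[lo] - sd3n) / (sd2n - sd3n)
  }
  out
}

#' Measurement at a given z-score (inverse LMS transform)
#'
#' @param z numeric z-score vector.
#' @param L,M,S LMS parameters (recycled).
#' @return The measurement `y = M (1 + L S z)^(1/L)` (`M exp(S z)` when
#'   `L = 0`). Round-trips with [lms_zscore()] (unrestricted) to 1e-9
#'   relative. The argument region `1 + L S z <= 0` (unreachable for
#'   realistic references) is a domain error.
#' @export
lms_inverse_zscore <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(as.numeric(z), n); L <- rep_len(as.numeric(L), n)
  M <- rep_len(as.numeric(M), n); S <- rep_len(as.numeric(S), n)
  base <- 1 + L * S * z
  bad <- !is.na(base) & L != 0 & base <= 0
  if (any(bad)) {
    stop_pdc("z = %g outside the domain of the inverse LMS transform (1 + L*S*z <= 0)",
             z[which(bad)[1L]], class = "pdc_domain_error")
  }
  ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
}

#' Z-score against a reference table
#'
#' Convenience wrapper: interpolates the table at `index_value` and applies
#' [lms_zscore()]. The restricted adjustment is applied to weight-based
#' indicators (weight-for-age, weight-for-length) only, never to
#' length-for-age, following the WHO igrowup convention.
#'
#' @param table an [lms_table()].
#' @param y measurement vector (kg or cm to match the table).
#' @param index_value age in days or length in cm, per the table's
#'   `index_kind`.
#' @param restricted `"auto"` (default: by indicator), `TRUE` or `FALSE`.
#' @return numeric z-scores; NA where the index is out of the reference
#'   range or inputs are missing.
#' @export
reference_zscore <- function(table, y, index_value, restricted = "auto") {
  stopifnot(inherits(table, "lms_table"))
  if (identical(restricted, "auto")) {
    restricted <- attr(table, "indicator") %in% c("weight_for_age", "weight_for_length")
  }
  p <- interpolate_lms(table, index_value, strict = FALSE)
  lms_zscore(y, p$L, p$M, p$S, restricted = restricted)
}
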