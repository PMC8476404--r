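# Reading and writing WHO-style LMS reference files, and the synthetic
# reference set bundled for self-contained runs.

#' Read a WHO-style LMS reference file
#'
#' Accepts the common text dialect of LMS reference tables: a header row
#' and tab- or comma-delimited columns `sex, index, L, M, S` (the index
#' column may be named `age`, `day`, `days`, `length`, `height` or
#' `index`). The sex column may be coded `1`/`2` or `m`/`f` (any case,
#' full words accepted). Real WHO 2006 files are drop-in; the bundled
#' fixture is synthetic.
#'
#' @param path file path.
#' @param indicator which indicator the file describes.
#' @param sex which sex to extract (files may hold both).
#' @return An [lms_table()].
#' @export
read_lms_table <- function(path, indicator, sex) {
  indicator <- match.arg(indicator, INDICATORS)
  sex <- match.arg(sex, SEXES)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  idx_col <- intersect(c("index", "age", "day", "days", "agedays",
                         "length", "height", "lenhei"), names(raw))
  if (length(idx_col) == 0L || !all(c("l", "m", "s") %in% names(raw))) {
    stop_pdc("LMS file %s must have columns sex|index|L|M|S (index may be named age/length)",
             path, class = "pdc_schema_error")
  }
  if ("sex" %in% names(raw)) {
    sx <- tolower(as.character(raw$sex))
    sx <- ifelse(sx %in% c("1", "m", "male"), "male",
          ifelse(sx %in% c("2", "f", "female"), "female", NA))
    if (anyNA(sx)) {
      stop_pdc("unrecognised sex codes in %s", path, class = "pdc_schema_error")
    }
    raw <- raw[sx == sex, , drop = FALSE]
  }
  if (nrow(raw) == 0L) {
    stop_pdc("no rows for sex '%s' in %s", sex, path, class = "pdc_schema_error")
  }
  raw <- raw[order(raw[[idx_col[1L]]]), , drop = FALSE]
  lms_table(indicator, sex, raw[[idx_col[1L]]], raw$l, raw$m, raw$s)
}

#' Write an LMS table in the portable text dialect
#'
#' @param table an [lms_table()].
#' @param path output file path (CSV with header `sex,index,L,M,S`).
#' @return `path`, invisibly.
#' @export
write_lms_table <- function(table, path) {
  stopifnot(inherits(table, "lms_table"))
  out <- data.frame(sex = attr(table, "sex"), index = table$index,
                    L = table$L, M = table$M, S = table$S)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Smooth parametric LMS curves loosely shaped like infant growth in the
# first two years. Deliberately synthetic: close enough in location and
# spread for realistic simulation and audit exercises, but NOT the WHO
# 2006 standard (real WHO files load through read_lms_table()). The
# weight-for-length median is built by composing the other two medians
# (weight median at the age whose length median equals the given
# length), so the three indicators are mutually consistent: a child on
# the length and weight medians is also on the weight-for-length median.
synthetic_lms_curves <- function(indicator, sex, index) {
  f <- sex == "female"
  wfa_M <- function(a) (3.35 - 0.15 * f) + (7.2 - 0.55 * f) * (1 - exp(-a / 185))
  lfa_M0 <- 49.9 - 0.7 * f
  lfa_span <- 31.5 - 1.0 * f
  lfa_M <- function(a) lfa_M0 + lfa_span * (1 - exp(-a / 275))
  age_at_length <- function(l) -275 * log(1 - (l - lfa_M0) / lfa_span)
  switch(indicator,
    weight_for_age = {
      M <- wfa_M(index)
      L <- rep(0.25, length(index))
      S <- 0.125 + 0.015 * exp(-index / 200)
    },
    length_for_age = {
      M <- lfa_M(index)
      L <- rep(1, length(index))
      S <- 0.037 + 0.004 * (index / 730)
    },
    weight_for_length = {
      l_hi <- lfa_M(730)
      M <- numeric(length(index))
      lo <- index < lfa_M0
      hi <- index > l_hi
      mid <- !lo & !hi
      # below the birth-length median: allometric weight ~ length^2.2
      M[lo] <- wfa_M(0) * (index[lo] / lfa_M0)^2.2
      M[mid] <- wfa_M(age_at_length(index[mid]))
      # past the 24-month span: continue with the end slope
      slope_end <- (wfa_M(730) - wfa_M(age_at_length(l_hi - 0.5))) / 0.5
      M[hi] <- wfa_M(730) + slope_end * (index[hi] - l_hi)
      L <- rep(-0.35, length(index))
      S <- 0.11 - 0.00025 * (index - 50)
    })
  list(L = L, M = M, S = S)
}

#' Synthetic growth reference set
#'
#' Builds the full set of six LMS tables (three indicators x two sexes)
#' from smooth parametric curves that resemble infant growth in location
#' and spread. These are synthetic references for simulation, testing and
#' demonstration -- they are not the WHO 2006 Child Growth Standards,
#' which can be supplied as drop-in files via [read_lms_table()].
#'
#' @param age_step grid step in days for the age-indexed tables
#'   (default 7; span 0..730 days).
#' @param length_step grid step in cm for weight-for-length
#'   (default 0.5; span 40..110 cm).
#' @return A named list `refs[[indicator]][[sex]]` of [lms_table()]
#'   objects.
#' @export
synthetic_reference <- function(age_step = 7, length_step = 0.5) {
  ages <- seq(0, 730, by = age_step)
  lens <- seq(40, 110, by = length_step)
  out <- list()
  for (ind in INDICATORS) {
    out[[ind]] <- list()
    idx <- if (ind == "weight_for_length") lens else ages
    for (sx in SEXES) {
      p <- synthetic_lms_curves(ind, sx, idx)
      out[[ind]][[sx]] <- lms_table(ind, sx, idx, p$L, p$M, p$S)
    }
  }
  out
}

#' Read a full reference set from a directory
#'
#' Expects files `<indicator>.csv` (e.g. `weight_for_age.csv`) in the
#' dialect of [write_lms_table()], each holding both sexes.
#'
#' @param dir directory containing the three indicator files.
#' @return A reference set as returned by [synthetic_reference()].
#' @export
read_reference_set <- function(dir) {
  out <- list()
  for (ind in INDICATORS) {
    path <- file.path(dir, paste0(ind, ".csv"))
    if (!file.exists(path)) {
      stop_pdc("missing reference file %s", path, class = "pdc_schema_error")
    }
    out[[ind]] <- list(male = read_lms_table(path, ind, "male"),
                       female = read_lms_table(path, ind, "female"))
  }
  out
}

#' Write a full reference set to a directory
#'
#' @param refs a reference set (see [synthetic_reference()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ind in names(refs)) {
    path <- file.path(dir, paste0(ind, ".csv"))
    rows <- lapply(refs[[ind]], function(tb) {
      data.frame(sex = attr(tb, "sex"), index = tb$index,
                 L = tb$L, M = tb$M, S = tb$S)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
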