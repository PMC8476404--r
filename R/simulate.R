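# Seeded synthetic EMR generator: cohorts with the statistical structure
# the audit and difference-in-difference stages assume (pre/post x
# control/intervention design, preterm case mix, clinic visit schedule,
# nurse recording behaviour with missingness, misclassification and
# occasional implausible entries).

#' Default study-period windows
#'
#' Six-month pre- and post-intervention windows separated by a six-month
#' gap, mirroring a two-phase quasi-experimental design.
#' @return Named list of `Date` pairs `pre` and `post`.
#' @export
default_periods <- function() {
  list(pre = as.Date(c("2017-08-01", "2018-01-31")),
       post = as.Date(c("2018-08-01", "2019-01-31")))
}

#' Label dates with their study period
#'
#' Adds `period` to visits (from `visit_date`) and `enrollment_period`
#' to children (from `enrollment_date`): `"pre"`, `"post"`, or NA when
#' the date falls outside both windows.
#'
#' @param children,visits ingest tables.
#' @param periods window list as from [default_periods()].
#' @return `list(children, visits)` with the period columns added.
#' @export
assign_periods <- function(children, visits, periods = default_periods()) {
  lab <- function(d) {
    ifelse(d >= periods$pre[1] & d <= periods$pre[2], "pre",
    ifelse(d >= periods$post[1] & d <= periods$post[2], "post", NA_character_))
  }
  visits$period <- lab(as.Date(visits$visit_date))
  children$enrollment_period <- lab(as.Date(children$enrollment_date))
  list(children = children, visits = visits)
}

default_facilities <- function() {
  data.frame(
    facility_id = c("C-DH", paste0("C-HC", 1:4), "I-DH", paste0("I-HC", 1:3)),
    arm = c(rep("control", 5), rep("intervention", 4)),
    facility_type = c("hospital", rep("health_centre", 4),
                      "hospital", rep("health_centre", 3)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Builds the configuration object for [simulate_cohort()]. Defaults
#' describe a two-district clinic network audited over a pre/post
#' quasi-experiment: cohort sizes and facility mixes of a realistic
#' programme, a preterm-heavy case mix, the standard follow-up schedule
#' (1, 2, 3 weeks; 1, 2, 4, 6, 9, 12 months), child-level latent growth
#' (per-child z intercept with AR(1) visit-to-visit noise), and nurse
#' recording behaviour (per-metric completion and per-group
#' misclassification probabilities, occasional implausible entries).
#'
#' @param seed integer RNG seed; the generator is deterministic given
#'   the seed and configuration.
#' @param n_children named vector of children per exposure group.
#' @param facilities data frame `facility_id`, `arm`, `facility_type`.
#' @param p_hospital per-group probability that a child enrols at the
#'   district hospital rather than a health centre.
#' @param preterm_fraction share of children born < 37 weeks.
#' @param p_ga_documented probability a preterm child's gestational age
#'   is documented (others are referred as preterm with GA missing).
#' @param ga_preterm,ga_term mean/sd/truncation (weeks) of gestational
#'   age within the preterm and term strata.
#' @param birthweight_model `intercept_g` and `slope_g_per_week` of mean
#'   birthweight against weeks below 40, plus `sd_g` and `min_g`.
#' @param schedule_days chronological ages (days) of scheduled visits.
#' @param attendance_prob probability each scheduled visit occurs.
#' @param z_mu,z_sd means and SDs of per-child latent z intercepts for
#'   `lfa` and `wfa`.
#' @param ar1_rho,ar1_sd AR(1) correlation and innovation SD of
#'   visit-level z noise (growth tracking across visits).
#' @param weight_noise_g,length_noise_cm measurement noise SDs.
#' @param completion metric x group matrix of nurse recording
#'   probabilities (rows `weight`, `length`, `corrected_age`, `lhfa`,
#'   `wflh`, `wfa`, `interval_growth`).
#' @param misclassification per-group probability that a recorded
#'   category differs from the gold-standard class.
#' @param p_continuous_interval probability an interval-growth entry is
#'   recorded as a continuous g/day value instead of a category.
#' @param implausible_prob probability a visit's weight is entered with
#'   a slipped decimal (x10), producing an implausible z-score.
#' @param periods study windows (see [default_periods()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1L,
    n_children = c(control_pre = 214, control_post = 151,
                   intervention_pre = 288, intervention_post = 227),
    facilities = default_facilities(),
    p_hospital = c(control_pre = 0.29, control_post = 0.25,
                   intervention_pre = 0.91, intervention_post = 0.57),
    preterm_fraction = 0.57,
    p_ga_documented = 0.85,
    ga_preterm = c(mean = 33.5, sd = 2.5, lo = 26, hi = 36.9),
    ga_term = c(mean = 39.2, sd = 1.1, lo = 37, hi = 42),
    birthweight_model = c(intercept_g = 3300, slope_g_per_week = 210,
                          sd_g = 350, min_g = 700),
    schedule_days = c(7, 14, 21, 30.4, 60.9, 121.8, 182.6, 273.9, 365.25),
    attendance_prob = 0.85,
    z_mu = c(lfa = -1.9, wfa = -1.8),
    z_sd = c(lfa = 1.1, wfa = 1.1),
    ar1_rho = 0.7,
    ar1_sd = 0.35,
    weight_noise_g = 30,
    length_noise_cm = 0.3,
    completion = NULL,
    misclassification = c(control_pre = 0.32, control_post = 0.33,
                          intervention_pre = 0.17, intervention_post = 0.22),
    p_continuous_interval = 0.15,
    implausible_prob = 0.005,
    periods = default_periods()) {
  if (is.null(completion)) {
    completion <- rbind(
      weight          = c(1.00, 1.00, 1.00, 1.00),
      length          = c(0.99, 0.99, 1.00, 0.99),
      corrected_age   = c(0.51, 0.55, 0.06, 0.65),
      lhfa            = c(0.77, 0.57, 0.79, 0.82),
      wflh            = c(0.76, 0.59, 0.78, 0.90),
      wfa             = c(0.77, 0.67, 0.79, 0.93),
      interval_growth = c(0.81, 0.81, 0.82, 0.90))
    colnames(completion) <- EXPOSURE_GROUPS
  }
  cfg <- list(seed = as.integer(seed), n_children = n_children,
              facilities = facilities, p_hospital = p_hospital,
              preterm_fraction = preterm_fraction,
              p_ga_documented = p_ga_documented,
              ga_preterm = ga_preterm, ga_term = ga_term,
              birthweight_model = birthweight_model,
              schedule_days = schedule_days,
              attendance_prob = attendance_prob,
              z_mu = z_mu, z_sd = z_sd, ar1_rho = ar1_rho, ar1_sd = ar1_sd,
              weight_noise_g = weight_noise_g,
              length_noise_cm = length_noise_cm,
              completion = completion,
              misclassification = misclassification,
              p_continuous_interval = p_continuous_interval,
              implausible_prob = implausible_prob,
              periods = periods)
  probs <- c(attendance_prob, p_ga_documented, preterm_fraction,
             completion, misclassification, p_continuous_interval,
             implausible_prob, p_hospital)
  if (any(probs < 0 | probs > 1)) {
    stop_pdc("all probabilities must lie in [0, 1]", class = "pdc_config_error")
  }
  if (is.unsorted(schedule_days, strictly = TRUE)) {
    stop_pdc("visit schedule must be strictly increasing", class = "pdc_config_error")
  }
  class(cfg) <- "sim_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

# Pick a wrong category uniformly among the alternatives.
corrupt_class <- function(gold, classes) {
  vapply(gold, function(g) {
    alt <- setdiff(classes, g)
    alt[sample.int(length(alt), 1L)]
  }, character(1))
}

#' Simulate a synthetic PDC-like cohort
#'
#' Generates children, their clinic visits and a truth table. True
#' lengths and weights are produced by drawing latent length-for-age and
#' weight-for-age z trajectories (per-child intercept plus AR(1) visit
#' noise) and inverting the reference tables at the visit's corrected
#' age (clamped at 0 before term), then adding measurement noise. Nurse
#' records are derived from the gold-standard classification of the
#' recorded measurements by thinning (per-metric completion
#' probability), corrupting (per-group misclassification probability)
#' and occasional implausible data entry (weight x10).
#'
#' @param config a [sim_config()].
#' @param references a reference set (see [synthetic_reference()]).
#' @return `list(children, visits, truth)`; `truth` holds the
#'   generating z values and gold classes per visit for recovery tests.
#' @export
simulate_cohort <- function(config = sim_config(), references = synthetic_reference()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fac <- config$facilities
  children <- list(); visits <- list(); truth <- list()
  id_counter <- 0L

  for (grp in EXPOSURE_GROUPS) {
    arm <- sub("_(pre|post)$", "", grp)
    per <- sub("^.*_", "", grp)
    window <- config$periods[[per]]
    n <- config$n_children[[grp]]
    arm_fac <- fac[fac$arm == arm, , drop = FALSE]
    hosp <- arm_fac[arm_fac$facility_type == "hospital", , drop = FALSE]
    hcs <- arm_fac[arm_fac$facility_type == "health_centre", , drop = FALSE]

    for (j in seq_len(n)) {
      id_counter <- id_counter + 1L
      cid <- sprintf("CH%05d", id_counter)
      preterm <- stats::runif(1) < config$preterm_fraction
      ga_par <- if (preterm) config$ga_preterm else config$ga_term
      ga <- round(rtrunc_norm(1, ga_par["mean"], ga_par["sd"],
                              ga_par["lo"], ga_par["hi"]) * 7) / 7
      ga_documented <- !preterm || stats::runif(1) < config$p_ga_documented
      bwm <- config$birthweight_model
      bw <- max(bwm["min_g"],
                stats::rnorm(1, bwm["intercept_g"] - bwm["slope_g_per_week"] *
                               (40 - ga), bwm["sd_g"]))
      sex <- sample(SEXES, 1L)
      enrol_date <- as.Date(floor(stats::runif(1, as.numeric(window[1]),
                                               as.numeric(window[2]) + 1)),
                            origin = "1970-01-01")
      enrol_age <- sample(3:21, 1L)
      birth_date <- enrol_date - enrol_age
      use_hosp <- stats::runif(1) < config$p_hospital[[grp]] && nrow(hosp) > 0
      frow <- if (use_hosp) hosp[1L, ] else hcs[sample.int(nrow(hcs), 1L), ]

      children[[id_counter]] <- data.frame(
        child_id = cid, birth_date = birth_date,
        gestational_age_weeks = if (ga_documented) round(ga, 2) else NA_real_,
        referred_as_preterm = preterm,
        birthweight_g = round(bw),
        enrollment_date = enrol_date, sex = sex,
        facility_id = frow$facility_id, facility_type = frow$facility_type,
        arm = arm, stringsAsFactors = FALSE)

      # latent z trajectories over the attended schedule
      attend <- stats::runif(length(config$schedule_days)) < config$attendance_prob
      days <- config$schedule_days[attend]
      if (length(days) == 0L) next
      nv <- length(days)
      z0 <- stats::rnorm(2, config$z_mu, config$z_sd)
      eps <- matrix(stats::rnorm(2 * nv, 0, config$ar1_sd), nrow = 2)
      zt <- matrix(NA_real_, nrow = 2, ncol = nv)
      zt[, 1] <- z0 + eps[, 1]
      if (nv > 1) for (k in 2:nv) {
        zt[, k] <- z0 + config$ar1_rho * (zt[, k - 1] - z0) + eps[, k]
      }

      corr_days <- round(days) -
        if (preterm) as.integer(round_half_up(7 * (40 - ga))) else 0L
      gen_age <- pmax(corr_days, 0)
      lfa_tab <- references$length_for_age[[sex]]
      wfa_tab <- references$weight_for_age[[sex]]
      p_l <- interpolate_lms(lfa_tab, gen_age, strict = FALSE)
      p_w <- interpolate_lms(wfa_tab, gen_age, strict = FALSE)
      len_true <- lms_inverse_zscore(zt[1, ], p_l$L, p_l$M, p_l$S)
      wt_true <- lms_inverse_zscore(zt[2, ], p_w$L, p_w$M, p_w$S) * 1000
      len_rec <- round(len_true + stats::rnorm(nv, 0, config$length_noise_cm), 1)
      wt_rec <- round(wt_true + stats::rnorm(nv, 0, config$weight_noise_g), -1)
      slip <- stats::runif(nv) < config$implausible_prob
      wt_rec[slip] <- wt_rec[slip] * 10

      visit_dates <- birth_date + round(days)
      comp <- config$completion[, grp]
      q <- config$misclassification[[grp]]
      child_rec <- children[[id_counter]]
      prev_wt <- NA_real_; prev_date <- as.Date(NA)
      for (k in seq_len(nv)) {
        wt_k <- if (stats::runif(1) < comp["weight"]) wt_rec[k] else NA_real_
        ln_k <- if (stats::runif(1) < comp["length"]) len_rec[k] else NA_real_
        vrow <- list(visit_date = visit_dates[k], weight_g = wt_k,
                     length_cm = ln_k)
        prev <- if (!is.na(prev_wt))
          list(visit_date = prev_date, weight_g = prev_wt) else NULL
        gold <- assess_visit(child_rec, vrow, prev, references)

        # a recorded category is the gold class corrupted with prob q
        # (or a random category when the gold is uncomputable)
        rec_cat <- function(gold_class, classes) {
          if (is.na(gold_class)) return(sample(classes, 1L))
          if (stats::runif(1) < q) corrupt_class(gold_class, classes)
          else gold_class
        }
        thin <- function(metric) stats::runif(1) < comp[metric]
        n_lhfa <- if (thin("lhfa")) rec_cat(gold$class_lhfa, ZSCORE_CLASSES) else NA_character_
        n_wflh <- if (thin("wflh")) rec_cat(gold$class_wflh, ZSCORE_CLASSES) else NA_character_
        n_wfa <- if (thin("wfa")) rec_cat(gold$class_wfa, ZSCORE_CLASSES) else NA_character_
        n_int_cat <- NA_character_; n_int_val <- NA_real_
        if (thin("interval_growth")) {
          if (!is.na(gold$interval_growth_g_per_day) &&
              stats::runif(1) < config$p_continuous_interval) {
            n_int_val <- round(gold$interval_growth_g_per_day, 1)
          } else {
            n_int_cat <- rec_cat(gold$class_interval, INTERVAL_CLASSES)
          }
        }
        visits[[length(visits) + 1L]] <- data.frame(
          child_id = cid, visit_date = visit_dates[k],
          visit_type = "standard_growth",
          weight_g = wt_k, length_cm = ln_k,
          nurse_corrected_age_recorded = stats::runif(1) < comp["corrected_age"],
          nurse_lhfa = n_lhfa, nurse_wflh = n_wflh, nurse_wfa = n_wfa,
          nurse_interval_growth_category = n_int_cat,
          nurse_interval_growth_value = n_int_val,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          child_id = cid, visit_date = visit_dates[k],
          z_lfa_true = zt[1, k], z_wfa_true = zt[2, k],
          gold_lhfa = gold$class_lhfa, gold_wflh = gold$class_wflh,
          gold_wfa = gold$class_wfa, gold_interval = gold$class_interval,
          implausible_injected = slip[k], stringsAsFactors = FALSE)
        if (!is.na(wt_k)) { prev_wt <- wt_k; prev_date <- visit_dates[k] }
      }
    }
  }
  children <- do.call(rbind, children)
  visits <- do.call(rbind, visits)
  truth <- do.call(rbind, truth)
  lab <- assign_periods(children, visits, config$periods)
  list(children = lab$children, visits = lab$visits, truth = truth)
}

#' Simulate a difference-in-difference scenario
#'
#' Child-level binary outcomes with specified cell probabilities,
#' facility-level random intercepts and a known arm x period
#' interaction, for exercising [did_fit()].
#'
#' @param seed integer seed.
#' @param n_facilities total facilities, split evenly between arms.
#' @param children_per_cell children per facility per period.
#' @param base_prob outcome probability in the control-pre cell.
#' @param arm_effect,period_effect additive shifts for the intervention
#'   arm and the post period.
#' @param interaction_effect additional shift in intervention-post (the
#'   generating difference-in-difference).
#' @param facility_sd SD of additive facility random intercepts
#'   (truncated at +/- 2 SD to keep probabilities in range).
#' @param hospital_fraction share of facilities typed as hospitals.
#' @return Data frame of rows for [did_fit()]: `outcome`, `arm`,
#'   `period`, `facility_id`, `facility_type`.
#' @export
simulate_did_scenario <- function(seed = 1L, n_facilities = 20,
                                  children_per_cell = 50,
                                  base_prob = 0.5, arm_effect = 0,
                                  period_effect = 0,
                                  interaction_effect = 0,
                                  facility_sd = 0.05,
                                  hospital_fraction = 0.2) {
  set.seed(seed)
  cells <- expand.grid(arm = c("control", "intervention"),
                       period = c("pre", "post"), stringsAsFactors = FALSE)
  cells$p <- base_prob +
    arm_effect * (cells$arm == "intervention") +
    period_effect * (cells$period == "post") +
    interaction_effect * (cells$arm == "intervention" & cells$period == "post")
  lim <- 2 * facility_sd
  if (any(cells$p - lim < 0 | cells$p + lim > 1)) {
    stop_pdc("cell probabilities fall outside [0, 1] after effects",
             class = "pdc_config_error")
  }
  per_arm <- n_facilities %/% 2
  fac <- data.frame(
    facility_id = sprintf("F%02d", seq_len(n_facilities)),
    arm = rep(c("control", "intervention"), times = c(per_arm, n_facilities - per_arm)),
    facility_type = ifelse(stats::runif(n_facilities) < hospital_fraction,
                           "hospital", "health_centre"),
    u = pmax(pmin(stats::rnorm(n_facilities, 0, facility_sd), lim), -lim),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(fac))) {
    for (per in c("pre", "post")) {
      p <- cells$p[cells$arm == fac$arm[i] & cells$period == per] + fac$u[i]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = as.integer(stats::runif(children_per_cell) < p),
        arm = fac$arm[i], period = per,
        facility_id = fac$facility_id[i],
        facility_type = fac$facility_type[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
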