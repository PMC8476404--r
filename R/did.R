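# Difference-in-difference estimation on binary outcomes: linear
# probability model with an arm x period interaction and
# facility-clustered robust standard errors.

#' Difference-in-difference fit for a binary outcome
#'
#' Fits the linear probability model
#' `outcome ~ arm + period + arm:period` (optionally plus facility type)
#' by OLS and reports the interaction coefficient -- the
#' difference-in-difference, interpretable in percentage points/100 --
#' with a cluster-robust sandwich standard error over facilities and a
#' two-sided p-value from a t distribution with (clusters - 1) degrees
#' of freedom. In the unadjusted (saturated) model the interaction
#' equals the four-cell closed form
#' `(p[I,post] - p[I,pre]) - (p[C,post] - p[C,pre])` exactly.
#'
#' @param rows data frame with columns `outcome` (0/1 or logical;
#'   missing values dropped listwise), `arm` (`control`/`intervention`),
#'   `period` (`pre`/`post`), `facility_id`, and `facility_type`
#'   (`hospital`/`health_centre`, required when `adjust = TRUE`).
#' @param outcome_name label carried into the result.
#' @param adjust add facility type as a covariate (the facility-mix
#'   sensitivity analysis).
#' @param cr_type small-sample correction for the clustered variance:
#'   `"CR1"` (default) scales the meat by
#'   `G/(G-1) * (n-1)/(n-k)` (the Stata `vce(cluster)` convention);
#'   `"CR0"` applies no correction.
#' @return A `did_result` (list): `outcome_name`, `beta_interaction`,
#'   `se_clustered`, `p_value`, `n_obs`, `n_clusters`,
#'   `adjusted_for_facility_type`, `group_means` (the four cell
#'   proportions) and the underlying `fit`.
#' @export
did_fit <- function(rows, outcome_name = "outcome", adjust = FALSE,
                    cr_type = c("CR1", "CR0")) {
  cr_type <- match.arg(cr_type)
  rows <- as.data.frame(rows)
  rows$outcome <- as.numeric(rows$outcome)
  rows <- rows[!is.na(rows$outcome), , drop = FALSE]
  rows$arm <- factor(match_arg_chr(rows$arm, c("control", "intervention"), "arm"),
                     levels = c("control", "intervention"))
  rows$period <- factor(match_arg_chr(rows$period, c("pre", "post"), "period"),
                        levels = c("pre", "post"))
  cells <- table(rows$arm, rows$period)
  if (any(cells == 0)) {
    stop_pdc("all four arm x period cells must be non-empty",
             class = "pdc_design_error")
  }
  G <- length(unique(rows$facility_id))
  if (G < 2) {
    stop_pdc("cluster-robust inference needs at least 2 facilities",
             class = "pdc_inference_error")
  }
  fml <- if (adjust) outcome ~ arm * period + facility_type else outcome ~ arm * period
  fit <- stats::lm(fml, data = rows)
  meat <- sandwich::vcovCL(fit, cluster = rows$facility_id,
                           type = "HC0", cadjust = FALSE)
  n <- nrow(rows)
  k <- length(stats::coef(fit))
  V <- switch(cr_type,
    CR0 = meat,
    CR1 = meat * (G / (G - 1)) * ((n - 1) / (n - k)))
  term <- "armintervention:periodpost"
  beta <- unname(stats::coef(fit)[term])
  se <- sqrt(V[term, term])
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = G - 1)
  gm <- tapply(rows$outcome, list(rows$arm, rows$period), mean)
  structure(list(
    outcome_name = outcome_name,
    beta_interaction = beta,
    se_clustered = se,
    p_value = p,
    n_obs = n,
    n_clusters = G,
    adjusted_for_facility_type = adjust,
    cr_type = cr_type,
    group_means = c(control_pre = gm["control", "pre"],
                    control_post = gm["control", "post"],
                    intervention_pre = gm["intervention", "pre"],
                    intervention_post = gm["intervention", "post"]),
    fit = fit), class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf("Difference-in-difference: %s\n", x$outcome_name))
  cat(sprintf("  interaction = %+.4f (%.1f pp), clustered SE = %.4f, p = %.4g\n",
              x$beta_interaction, 100 * x$beta_interaction, x$se_clustered,
              x$p_value))
  cat(sprintf("  n = %d observations, %d facility clusters%s (%s)\n", x$n_obs,
              x$n_clusters,
              if (x$adjusted_for_facility_type) ", adjusted for facility type" else "",
              x$cr_type))
  gm <- x$group_means
  cat(sprintf("  cell means: C-pre %.3f, C-post %.3f, I-pre %.3f, I-post %.3f\n",
              gm[1], gm[2], gm[3], gm[4]))
  invisible(x)
}

#' Summarise several DiD fits as a table
#'
#' @param fits list of `did_result` objects.
#' @return Data frame with one row per outcome: estimate, SE, p-value,
#'   sizes.
#' @export
did_table <- function(fits) {
  do.call(rbind, lapply(fits, function(x) {
    data.frame(outcome = x$outcome_name,
               beta_interaction = x$beta_interaction,
               se_clustered = x$se_clustered,
               p_value = x$p_value,
               n_obs = x$n_obs, n_clusters = x$n_clusters,
               adjusted = x$adjusted_for_facility_type)
  }))
}
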